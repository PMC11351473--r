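---
title: "Methods: presence-background habitat models and environmental-space niche overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background habitat models and environmental-space niche overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SDMNiche)
```

SDMNiche implements a complete workflow for two questions ecologists ask
about sympatric species: *where* is each species' suitable habitat, and *how
much* do their environmental niches overlap? The workflow is: occurrence
thinning, covariate screening, a replicated maximum-entropy habitat model per
species, habitat binarization and overlap accounting, and kernel-smoothed
niche quantification in a principal-component environmental space. Because
real survey data are rarely shareable, the package also ships a synthetic
landscape-and-occurrence generator with *known* Gaussian niches, so every
stage can be validated against ground truth.

## 1. Data model and spatial conventions

Rasters (`RasterGrid`) store values with row 1 as the northernmost row and an
explicit lower-left origin and square cell size; cells are half-open,
`[x, x + cs) × [y, y + cs)`, so a point on a shared edge belongs to exactly
one cell. I/O uses the ESRI ASCII grid format; a stack of co-registered
layers (`EnvStack`) round-trips through a directory plus JSON manifest.
Occurrences (`OccurrenceSet`) are point records in map units.

Thinning (`thinOccurrences`) deduplicates records to one per grid cell
(default 30 m, anchored to the raster origin), keeping the first record in
input order. This is deterministic, idempotent, and invariant to appending
duplicates — properties the test suite checks directly.

## 2. Covariate screening

`pearsonMatrix` computes pairwise Pearson correlations over all valid cells
(or at supplied points), and `screenVariables` greedily retains variables in
a priority order, dropping any candidate whose absolute correlation with an
already-retained variable reaches the threshold (default |r| < 0.8 must hold
for every retained pair). The retained set therefore always satisfies the
pairwise constraint, which is asserted post hoc.

## 3. The maximum-entropy model

The model is written from scratch. Suitability is a Gibbs distribution over
the background cells,

$$ q(x) = \frac{\exp(\lambda' f(x))}{\sum_{x' \in \text{bg}} \exp(\lambda' f(x'))/n}, $$

with features $f$ built from the covariates: linear, quadratic, pairwise
product, and hinge, all min-max scaled to [0, 1] on the pooled
presence-plus-background values. Feature classes auto-enable with sample
size (linear always; quadratic at ≥ 10, hinge at ≥ 15, product at ≥ 80
presences), following standard MaxEnt practice.

Fitting maximizes the L1-penalized log likelihood

$$ \frac{1}{m}\sum_{\text{presence}} \lambda' f(x_i) \;-\;
   \log \frac{1}{n}\sum_{\text{bg}} e^{\lambda' f(x)} \;-\;
   \sum_j \beta_j |\lambda_j| $$

by cyclic coordinate descent: each coordinate takes a soft-thresholded
Newton step, accepted only if the exactly re-evaluated objective does not
decrease (with step halving otherwise), so the recorded gain trace is
monotone by construction. The penalty is
$\beta_j = \text{betaMultiplier} \times c_{\text{class}} \times
\max(\mathrm{sd}_{\text{presence}}(f_j), 0.05)/\sqrt{m}$ with
$c_{\text{hinge}} = 1.5$ and 1 otherwise. At $\lambda = 0$ the objective is
zero, so the objective value *is* the regularized training gain.

The logistic output is $q e^H / (1 + q e^H)$ where $H$ is the entropy of the
fitted background distribution; a completely uninformative model yields 0.5
everywhere.

**Hinge resolution.** The default is 8 hinge knots per variable and
direction. With 5 knots the piecewise-linear basis was visibly too coarse to
track smooth unimodal responses: on synthetic scenes the rank correlation
between fitted and generative suitability dropped to ≈ 0.87 on some seeds,
recovering to ≥ 0.96 at 8 knots. Eight knots is therefore the package
default; it remains configurable.

**Verification.** One-feature fits are compared against an exhaustive
$\lambda$ grid-search oracle (agreement to three decimals); gain traces are
asserted monotone; presences drawn from the background itself produce
logistic output within 0.05 of 0.5.

## 4. Replicate protocol and evaluation

`replicateProtocol` fits `nRep` (default 10) replicates on random 80/20
presence splits against a fixed background sample (default 5397 distinct
cells), reporting per-replicate training/test AUC, the cell-wise mean
logistic map, replicate-mean percent contribution (attributing each
coordinate-descent gain increment to the underlying variable; product
features split evenly), permutation importance, and jackknife gains.

AUC is the rank statistic (Mann–Whitney with half-weight ties). The maximum
TSS (sensitivity + specificity − 1) and the maximum sensitivity-plus-
specificity threshold are swept over distinct observed scores, taking the
lowest threshold on ties; both sweeps are tested against $O(n^2)$ brute-force
oracles on random inputs.

## 5. Habitat area and overlap

The mean logistic map is binarized at the maximum sensitivity-plus-
specificity threshold (boundary inclusive). Areas are cell counts times cell
area; `overlapStats` reports each species' suitable area, the intersection,
fractions of the study area, and the intersection as a share of each
species' habitat, both raw and rounded to reporting precision (areas 2 dp,
study-area fractions 2 dp, intersection shares 1 dp).

## 6. Variable elimination and the niche in environmental space

Per-variable importances of the two species are combined as
$\mathrm{SRSS}_v = \sqrt{\text{imp}_{A,v}^2 + \text{imp}_{B,v}^2}$ and sorted
descending (alphabetical tie-break). `eliminateAndSelect` repeatedly removes
the lowest-SRSS variable and refits a correlation-matrix PCA
(`eigen(cor(X))`, so eigenvalues sum to the number of variables) on the
background values, stopping at the first round where the first two
components explain more than 85% of variance **or** the third eigenvalue
falls below 1. Round 1 is the PCA on the full screened set; each logged
round records the PCA of the set remaining after that round's removal — a
package convention, stated here because the literature is ambiguous about
round indexing.

Occurrences are projected into the final background-calibrated PC1–PC2
plane. `buildEnvSpace` grids that plane (default 100 × 100 over the
background score range plus a 5% margin) and smooths occurrence and
background clouds with Gaussian kernels (per-axis normal-reference
bandwidth). Occupancy is occurrence density divided by availability where
availability exceeds $\tau \cdot \max$, normalized to sum 1.

**Support floor $\tau = 10^{-4}$.** Gaussian kernels have unbounded support,
so without a floor every grid cell carries positive occurrence density and
the 100%-contour niche breadth saturates at the whole availability support
for every species, making breadth comparisons meaningless. Density below
$\tau$ times the maximum is numerical tail mass, not niche, and is zeroed
for both the occurrence and availability surfaces.

Schoener's overlap is $D = 1 - \tfrac12 \sum |z_A - z_B|$ (0 disjoint, 1
identical); niche breadth at mass level $q$ is the number of cells in the
smallest density-ranked set holding mass $q$. `variableOverlap1d` gives the
analogous one-dimensional density overlap and peak locations per variable.

## 7. The synthetic scene

`generateEnvStack` builds FFT-smoothed Gaussian random fields, exactly
decorrelates them, and rotates by the Cholesky factor of a target
correlation matrix (default AR(1), ρ = 0.4, 14 continuous layers), plus
independent distance-to-feature layers (realized correlations are reported,
not imposed). `simulateOccurrences` draws cells with probability
proportional to a product-Gaussian response
$\exp(-\tfrac12 \sum ((v - \mu)/\sigma)^2)$, with replacement and sub-cell
jitter, so duplicates exercise the thinning stage. `defaultScene` plants two
species with overlapping niches — a well-sampled, wider-tolerance species A
(346 raw records) and a sparse, narrow species B (47) — on a 150 × 150 grid
of 30 m cells with 19 layers and a 5397-point background, sized so the full
pipeline runs in about a minute.

Sampling is verified distributionally: empirical cell frequencies converge
to normalized suitability in total-variation distance, occurrence means
match the analytic weighted mean, and flat suitability is uniform by a
chi-square test.

## 8. Reproducibility

`runPipeline(pipelineConfig(seed = s))` is deterministic given the seed: the
master seed expands into named per-stage seeds (`stageSeeds`), so changing,
say, the background draw does not perturb the landscape. `scripts/acceptance.R`
runs the whole pipeline for a given `--seed` and writes the headline
quantities as JSON.

## Limitations

- The MaxEnt implementation supports linear/quadratic/product/hinge features
  but not threshold or categorical features.
- Geographic I/O is ESRI ASCII grid only; no projection handling (all
  coordinates are assumed planar, in metres).
- Kernel bandwidths are normal-reference; heavily multimodal occurrence
  clouds may be over-smoothed.
- The elimination loop uses percent contribution as its importance input;
  contributions are path-dependent (they attribute gain increments along the
  optimization trace), so small importance differences should not be
  over-interpreted.
- Niche breadth counts grid cells, so values are comparable only within a
  fixed grid resolution and background calibration.
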