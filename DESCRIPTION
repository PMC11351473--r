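Package: SDMNiche
Title: Presence-Background Habitat Modelling and Environmental-Space Niche Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying suitable-habitat
    distribution and niche overlap of sympatric species from presence records
    and raster environmental covariates. Provides grid-based occurrence
    thinning, Pearson correlation screening of covariates, a from-scratch
    L1-regularized maximum-entropy (presence-background) habitat model with
    replicate evaluation (AUC, true skill statistic, jackknife importance,
    percent contribution, sensitivity-plus-specificity thresholding),
    habitat-area and overlap accounting, iterative PCA variable elimination
    ranked by the root-sum-of-squares of per-species importances, and
    kernel-smoothed niche construction in principal-component space with
    Schoener's D overlap. A synthetic-landscape generator produces correlated
    environmental layers and Gaussian-response occurrences so the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    MASS,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
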