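#' Specification of a synthetic landscape
#'
#' Describes the grid geometry and covariate structure of a generated scene:
#' `nContinuous` smoothed Gaussian random fields with a target correlation
#' matrix, plus `nDistance` distance-to-feature layers (Euclidean distance
#' from randomly placed points, emulating distance-from-road/settlement
#' covariates). Distance layers are generated independently; their realized
#' correlations are reported, not controlled.
#'
#' @param nRows,nCols grid dimensions (each >= 10).
#' @param cellSize cell edge in metres (default 30).
#' @param nContinuous number of correlated Gaussian-field layers.
#' @param nDistance number of distance-to-feature layers.
#' @param targetCorrelation symmetric positive-semidefinite correlation
#'   matrix (`nContinuous` x `nContinuous`); default AR(1)-like with rho 0.4.
#' @param smoothSigma Gaussian smoothing length of the fields, in cells.
#' @param seed RNG seed.
#' @return a `LandscapeSpec` list (class "LandscapeSpec").
#' @export
landscapeSpec <- function(nRows = 150, nCols = 150, cellSize = 30,
                          nContinuous = 14, nDistance = 5,
                          targetCorrelation = NULL, smoothSigma = 6,
                          seed = 1L) {
  if (nRows < 10 || nCols < 10) stop("grid must be at least 10 x 10")
  if (is.null(targetCorrelation))
    targetCorrelation <- 0.4 ^ abs(outer(seq_len(nContinuous),
                                         seq_len(nContinuous), "-"))
  R <- as.matrix(targetCorrelation)
  if (nrow(R) != nContinuous || ncol(R) != nContinuous)
    stop("targetCorrelation must be nContinuous x nContinuous")
  if (max(abs(R - t(R))) > 1e-8) stop("targetCorrelation must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) stop("targetCorrelation must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("targetCorrelation is not positive semidefinite (smallest eigenvalue %.6g)",
                 min(ev)))
  structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                 cellSize = cellSize, nContinuous = as.integer(nContinuous),
                 nDistance = as.integer(nDistance), targetCorrelation = R,
                 smoothSigma = smoothSigma, seed = as.integer(seed)),
            class = "LandscapeSpec")
}

#' Gaussian niche parameters for a synthetic species
#'
#' The species' suitability over the landscape is a product of Gaussian
#' responses, `s(cell) = maxSuitability * exp(-0.5 * sum_l ((v_l - optimum_l)
#' / tolerance_l)^2)` over the layers used.
#'
#' @param optimum named numeric vector: optimum value per layer (layer units).
#' @param tolerance named numeric vector: niche width per layer (> 0).
#' @param maxSuitability peak suitability in (0, 1].
#' @return a `NicheParams` list (class "NicheParams").
#' @export
nicheParams <- function(optimum, tolerance, maxSuitability = 1) {
  if (length(optimum) == 0L) stop("at least one layer must be used")
  if (is.null(names(optimum)) || any(!nzchar(names(optimum))))
    stop("optimum must be named by layer")
  if (!identical(sort(names(optimum)), sort(names(tolerance))))
    stop("optimum and tolerance must cover the same layers")
  if (any(tolerance <= 0)) stop("tolerances must be strictly positive")
  if (maxSuitability <= 0 || maxSuitability > 1)
    stop("maxSuitability must be in (0, 1]")
  structure(list(optimum = optimum, tolerance = tolerance[names(optimum)],
                 maxSuitability = maxSuitability,
                 layers = names(optimum)),
            class = "NicheParams")
}

# FFT-based Gaussian smoothing of a white-noise field (periodic boundary);
# output standardized to zero mean / unit sd.
smoothField <- function(nr, nc, sigma) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return((z - mean(z)) / stats::sd(z))
  gx <- stats::dnorm(pmin(0:(nr - 1), nr - (0:(nr - 1))), sd = sigma)
  gy <- stats::dnorm(pmin(0:(nc - 1), nc - (0:(nc - 1))), sd = sigma)
  K <- outer(gx, gy)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a synthetic environmental stack
#'
#' Continuous layers are smoothed Gaussian random fields given the target
#' cross-layer correlation via the Cholesky factor of the target matrix
#' (imposed before any nonlinear transform). Distance layers are the
#' Euclidean distance from a few randomly placed feature points.
#'
#' @param spec a [landscapeSpec()] object.
#' @return an [EnvStack-class] with layers `env1..envK` and `dist1..distM`;
#'   attribute `realizedCorrelation` reports the sample correlations of all
#'   layers.
#' @export
generateEnvStack <- function(spec) {
  stopifnot(inherits(spec, "LandscapeSpec"))
  set.seed(spec$seed)
  nr <- spec$nRows; nc <- spec$nCols
  fields <- lapply(seq_len(spec$nContinuous), function(i)
    smoothField(nr, nc, spec$smoothSigma))
  X <- do.call(cbind, lapply(fields, as.vector))
  # re-standardize then rotate to the target correlation
  X <- scale(X)
  L <- chol(spec$targetCorrelation + diag(1e-10, spec$nContinuous))
  # decorrelate the sample exactly so the target is matched closely
  W <- chol(stats::cov(X) + diag(1e-12, ncol(X)))
  Xw <- X %*% solve(W)
  Xc <- Xw %*% L
  layers <- list()
  for (i in seq_len(spec$nContinuous)) {
    nm <- sprintf("env%d", i)
    layers[[nm]] <- rasterGrid(matrix(Xc[, i], nr, nc),
                               cellSize = spec$cellSize, name = nm)
  }
  if (spec$nDistance > 0) {
    for (i in seq_len(spec$nDistance)) {
      nf <- sample(1:4, 1L)
      fr <- stats::runif(nf, 0.5, nr + 0.5)
      fc <- stats::runif(nf, 0.5, nc + 0.5)
      rows <- matrix(seq_len(nr), nr, nc)
      cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      d <- matrix(Inf, nr, nc)
      for (k in seq_len(nf))
        d <- pmin(d, sqrt((rows - fr[k])^2 + (cols - fc[k])^2))
      nm <- sprintf("dist%d", i)
      layers[[nm]] <- rasterGrid(d * spec$cellSize,
                                 cellSize = spec$cellSize, name = nm)
    }
  }
  out <- envStack(layers)
  vals <- stackValues(out)
  attr(out, "realizedCorrelation") <- stats::cor(vals)
  out
}

# Gaussian-response suitability surface over valid cells; NA elsewhere.
suitabilitySurface <- function(env, niche) {
  miss <- setdiff(niche$layers, layerNames(env))
  if (length(miss))
    stop(sprintf("niche uses layer(s) absent from stack: %s",
                 paste(miss, collapse = ", ")))
  d <- gridDim(env)
  mask <- validMask(env)
  s <- matrix(0, d[1], d[2])
  for (nm in niche$layers) {
    v <- gridValues(getLayer(env, nm))
    s <- s + ((v - niche$optimum[nm]) / niche$tolerance[nm])^2
  }
  s <- niche$maxSuitability * exp(-0.5 * s)
  s[!mask] <- NA_real_
  s
}

#' Simulate species occurrences from a Gaussian niche
#'
#' Cells are drawn with replacement with probability proportional to the
#' suitability surface; each draw is placed at the cell centre plus uniform
#' sub-cell jitter, so repeated draws of one cell survive as duplicates for
#' the thinning stage to remove.
#'
#' @param env an [EnvStack-class].
#' @param niche a [nicheParams()] object.
#' @param nPoints number of occurrence records (>= 1).
#' @param seed RNG seed.
#' @param species species label.
#' @param source source tag.
#' @return an [OccurrenceSet-class].
#' @export
simulateOccurrences <- function(env, niche, nPoints, seed = 1L,
                                species = "speciesA", source = "synthetic") {
  if (nPoints < 1) stop("nPoints must be >= 1")
  s <- suitabilitySurface(env, niche)
  w <- as.vector(s)
  ok <- which(!is.na(w) & w > 0)
  if (length(ok) == 0L || sum(w[ok]) <= 0)
    stop("suitability surface is zero everywhere; no occurrences can be drawn")
  set.seed(seed)
  # sample.int avoids sample()'s scalar-x convenience when only one cell
  # has positive suitability
  cells <- ok[sample.int(length(ok), nPoints, replace = TRUE, prob = w[ok])]
  d <- gridDim(env)
  row <- ((cells - 1L) %% d[1]) + 1L
  col <- ((cells - 1L) %/% d[1]) + 1L
  ctr <- cellCenter(env, row, col)
  cs <- cellSize(env)
  x <- ctr[, 1L] + stats::runif(nPoints, -cs / 2, cs / 2)
  y <- ctr[, 2L] + stats::runif(nPoints, -cs / 2, cs / 2)
  occurrenceSet(species, x, y, source)
}

#' Sample background (pseudo-absence) points
#'
#' Uniform sample of distinct valid cells without replacement; points are
#' placed at cell centres. Cells containing any point of `exclude` can be
#' removed from the candidate pool.
#'
#' @param env an [EnvStack-class].
#' @param n number of background points.
#' @param seed RNG seed.
#' @param exclude optional [OccurrenceSet-class] whose cells are excluded.
#' @return an [OccurrenceSet-class] with source "background".
#' @export
sampleBackground <- function(env, n, seed = 1L, exclude = NULL) {
  mask <- validMask(env)
  pool <- which(mask)
  if (!is.null(exclude)) {
    xy <- coords(exclude)
    idx <- cellIndex(env, xy[, 1L], xy[, 2L])
    keep <- !is.na(idx[, 1L])
    lin <- (idx[keep, 2L] - 1L) * nrow(mask) + idx[keep, 1L]
    pool <- setdiff(pool, lin)
  }
  if (n > length(pool))
    stop(sprintf("requested %d background points but only %d candidate cells available",
                 n, length(pool)))
  set.seed(seed)
  cells <- if (n == length(pool)) pool else sample(pool, n)
  d <- gridDim(env)
  row <- ((cells - 1L) %% d[1]) + 1L
  col <- ((cells - 1L) %/% d[1]) + 1L
  ctr <- cellCenter(env, row, col)
  occurrenceSet("background", ctr[, 1L], ctr[, 2L], "background")
}

#' Default synthetic scene
#'
#' A two-species scene matching the study design the package emulates:
#' 19 covariate layers (14 correlated fields + 5 distance layers) on 30 m
#' cells, a well-sampled wide-niche species (346 raw records) and a sparse
#' narrow-niche species (47 raw records), and 5397 background points.
#' Species A's tolerance is twice species B's, so A occupies the broader
#' niche.
#'
#' @param seed master seed; stage seeds are derived deterministically.
#' @param nRows,nCols grid dimensions.
#' @param nA,nB raw occurrence counts before thinning.
#' @param nBackground number of background points.
#' @return list with `env`, `occA`, `occB`, `background`, `nicheA`, `nicheB`.
#' @export
defaultScene <- function(seed = 1L, nRows = 150, nCols = 150,
                         nA = 346, nB = 47, nBackground = 5397) {
  seeds <- stageSeeds(seed)
  spec <- landscapeSpec(nRows = nRows, nCols = nCols, seed = seeds["landscape"])
  env <- generateEnvStack(spec)
  # niches on two moderately correlated field layers plus one distance layer;
  # widths calibrated so grid thinning removes ~20-25% of raw records (the
  # duplication level the emulated survey design produces) and species A's
  # niche is several-fold wider than B's
  nicheA <- nicheParams(
    optimum = c(env1 = 1.0, env5 = -0.5, dist1 = 3000),
    tolerance = c(env1 = 0.24, env5 = 0.30, dist1 = 720),
    maxSuitability = 1)
  nicheB <- nicheParams(
    optimum = c(env1 = 0.7, env5 = -0.35, dist1 = 2700),
    tolerance = c(env1 = 0.10, env5 = 0.12, dist1 = 290),
    maxSuitability = 1)
  occA <- simulateOccurrences(env, nicheA, nA, seed = seeds["occA"],
                              species = "speciesA")
  occB <- simulateOccurrences(env, nicheB, nB, seed = seeds["occB"],
                              species = "speciesB")
  bg <- sampleBackground(env, nBackground, seed = seeds["background"])
  list(env = env, occA = occA, occB = occB, background = bg,
       nicheA = nicheA, nicheB = nicheB, seed = seed)
}
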