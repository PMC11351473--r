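#' Rank variables by root-sum-of-squares importance
#'
#' Combines two species' per-variable importances into
#' `SRSS_v = sqrt(impA_v^2 + impB_v^2)` and sorts descending, ties broken
#' alphabetically by variable name.
#'
#' @param impA,impB named non-negative numeric vectors over the same
#'   variables (e.g. replicate-mean percent contributions).
#' @return data.frame of class "ImportanceTable" with columns variable,
#'   impA, impB, srss, ordered by descending srss.
#' @export
srssRank <- function(impA, impB) {
  if (!setequal(names(impA), names(impB))) {
    d <- c(setdiff(names(impA), names(impB)), setdiff(names(impB), names(impA)))
    stop(sprintf("importance tables cover different variables: %s",
                 paste(d, collapse = ", ")))
  }
  if (any(impA < 0) || any(impB < 0)) stop("importances must be non-negative")
  v <- sort(names(impA))
  srss <- sqrt(impA[v]^2 + impB[v]^2)
  ord <- order(-srss, v)
  out <- data.frame(variable = v[ord], impA = unname(impA[v][ord]),
                    impB = unname(impB[v][ord]), srss = unname(srss[ord]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ImportanceTable", "data.frame")
  out
}

#' Principal component analysis on the correlation matrix
#'
#' Columns are centred and scaled to unit variance using the calibration
#' (background) statistics, then the correlation matrix is
#' eigendecomposed, so eigenvalues sum to the number of variables.
#'
#' @param x numeric matrix (rows = background samples).
#' @return list of class "PCAResult": `eigenvalues`, `varianceFraction`
#'   (percent), `loadings` (variables x components), `center`, `scale`,
#'   `scores` (calibration rows projected), `cos2` (per-variable squared
#'   correlation with Dim1/Dim2).
#' @export
pcaFit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 rows")
  sds <- apply(x, 2L, stats::sd)
  const <- colnames(x)[sds == 0]
  if (length(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(const, collapse = ", ")))
    x <- x[, sds > 0, drop = FALSE]
  }
  if (nrow(x) < ncol(x))
    warning("fewer rows than columns: PCA computed but unstable")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  xs <- scale(x, center = ctr, scale = scl)
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  # sign convention: largest-loading entry of each component positive
  V <- eig$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  rownames(V) <- colnames(x)
  colnames(V) <- paste0("Dim", seq_len(ncol(V)))
  lam <- eig$values
  scores <- xs %*% V
  # cos2 of variables on the first two components: (loading * sqrt(lambda))^2
  corr <- sweep(V, 2L, sqrt(pmax(lam, 0)), "*")
  cos2 <- corr[, 1:min(2L, ncol(V)), drop = FALSE]^2
  structure(list(eigenvalues = lam,
                 varianceFraction = 100 * lam / sum(lam),
                 loadings = V, center = ctr, scale = scl,
                 scores = scores, cos2 = cos2),
            class = "PCAResult")
}

#' Project new samples into a fitted PCA space
#'
#' Uses the calibration centring/scaling, so occurrence rows live in the
#' background-calibrated space.
#'
#' @param pca a "PCAResult" from [pcaFit()].
#' @param x matrix with the PCA's variables as columns.
#' @return score matrix (rows x components).
#' @export
projectScores <- function(pca, x) {
  x <- as.matrix(x)[, rownames(pca$loadings), drop = FALSE]
  scale(x, center = pca$center, scale = pca$scale) %*% pca$loadings
}

#' Stop/continue decision of the variable-elimination loop
#'
#' A PCA round is accepted when the first two components explain more than
#' `cumThreshold` percent of the variance, or the third eigenvalue falls
#' below `eigThreshold`.
#'
#' @param cumulative cumulative variance percent of components 1 + 2.
#' @param lambda3 third eigenvalue (NA when fewer than 3 variables remain,
#'   treated as below threshold).
#' @param cumThreshold percent (default 85).
#' @param eigThreshold eigenvalue bound (default 1).
#' @return TRUE to stop (select this round), FALSE to continue eliminating.
#' @export
stopDecision <- function(cumulative, lambda3, cumThreshold = 85,
                         eigThreshold = 1) {
  (!is.na(cumulative) && cumulative > cumThreshold) ||
    (is.na(lambda3) || lambda3 < eigThreshold)
}

#' Iterative PCA variable elimination
#'
#' Starting from the full importance-ranked variable set, repeatedly removes
#' the variable with the lowest SRSS, refits a correlation-matrix PCA on the
#' background values of the remaining variables, and stops at the first
#' round whose PCA satisfies [stopDecision()] (or when `minVars` remain,
#' returned with a flag). Round 1 is the PCA on the full set before any
#' removal.
#'
#' @param bgValues background covariate matrix (named columns covering the
#'   importance table's variables).
#' @param importance an "ImportanceTable" from [srssRank()].
#' @param cumThreshold,eigThreshold stopping-rule parameters (default 85, 1).
#' @param minVars smallest allowed remaining set (default 3).
#' @return list of class "EliminationResult": `selected` (variable names),
#'   `pca` (final "PCAResult"), `log` (data.frame: round, removed,
#'   remaining, cumulative12, lambda3, selected), `forced` (TRUE if stopping
#'   never triggered before minVars).
#' @export
eliminateAndSelect <- function(bgValues, importance, cumThreshold = 85,
                               eigThreshold = 1, minVars = 3) {
  stopifnot(inherits(importance, "ImportanceTable"))
  vars <- importance$variable       # descending SRSS
  miss <- setdiff(vars, colnames(bgValues))
  if (length(miss))
    stop(sprintf("background matrix missing variable(s): %s",
                 paste(miss, collapse = ", ")))
  if (length(vars) < minVars + 1L)
    stop(sprintf("need more than minVars = %d variables to eliminate", minVars))
  remaining <- vars
  logRows <- list()
  round <- 0L
  removedName <- NA_character_
  repeat {
    round <- round + 1L
    pca <- pcaFit(bgValues[, remaining, drop = FALSE])
    lam <- pca$eigenvalues
    cum12 <- sum(pca$varianceFraction[1:min(2L, length(lam))])
    lam3 <- if (length(lam) >= 3L) lam[3L] else NA_real_
    stop_ <- stopDecision(cum12, lam3, cumThreshold, eigThreshold)
    forced <- !stop_ && length(remaining) <= minVars
    logRows[[round]] <- data.frame(
      round = round, removed = removedName, nRemaining = length(remaining),
      cumulative12 = cum12, lambda3 = lam3, selected = stop_ || forced,
      stringsAsFactors = FALSE)
    if (stop_ || forced) {
      log <- do.call(rbind, logRows)
      return(structure(list(selected = remaining, pca = pca, log = log,
                            forced = forced),
                       class = "EliminationResult"))
    }
    removedName <- remaining[length(remaining)]  # lowest SRSS remaining
    remaining <- remaining[-length(remaining)]
  }
}

#' Build the kernel-smoothed occupancy grid in environmental space
#'
#' Grids the background-calibrated Dim1/Dim2 plane into `r` x `r` cells over
#' the background score range (plus a 5% margin), smooths the occurrence
#' and background score clouds with a Gaussian kernel (per-axis normal
#' reference bandwidth), and forms the occupancy `z`: occurrence density
#' divided by availability where availability exceeds `tau * max`, then
#' normalized to sum 1 (`corrected = FALSE` skips the division).
#'
#' @param bgScores background score matrix (Dim1, Dim2 columns).
#' @param occScores occurrence score matrix for one species (>= 5 rows).
#' @param r grid resolution per axis (default 100).
#' @param corrected divide by availability density (default TRUE).
#' @param tau availability floor as a fraction of its maximum (default 1e-4).
#' @param species species label.
#' @return an [EnvSpaceGrid-class].
#' @export
buildEnvSpace <- function(bgScores, occScores, r = 100, corrected = TRUE,
                          tau = 1e-4, species = "species") {
  bg <- as.matrix(bgScores)[, 1:2, drop = FALSE]
  oc <- as.matrix(occScores)[, 1:2, drop = FALSE]
  if (nrow(oc) < 5L) stop("need at least 5 occurrence scores")
  inx <- range(bg[, 1L]); iny <- range(bg[, 2L])
  mx <- diff(inx) * 0.05; my <- diff(iny) * 0.05
  xlim <- c(inx[1L] - mx, inx[2L] + mx)
  ylim <- c(iny[1L] - my, iny[2L] + my)
  if (any(oc[, 1L] < xlim[1L] | oc[, 1L] > xlim[2L] |
          oc[, 2L] < ylim[1L] | oc[, 2L] > ylim[2L]))
    stop("occurrence scores fall outside the background envelope; check the projection")
  hOcc <- c(MASS::bandwidth.nrd(oc[, 1L]), MASS::bandwidth.nrd(oc[, 2L]))
  hBg <- c(MASS::bandwidth.nrd(bg[, 1L]), MASS::bandwidth.nrd(bg[, 2L]))
  # degenerate spread (e.g. all occurrences at one point): tiny bandwidth
  hOcc[hOcc <= 0] <- diff(xlim) / r
  hBg[hBg <= 0] <- diff(xlim) / r
  kOcc <- MASS::kde2d(oc[, 1L], oc[, 2L], h = hOcc, n = r,
                      lims = c(xlim, ylim))
  kBg <- MASS::kde2d(bg[, 1L], bg[, 2L], h = hBg, n = r, lims = c(xlim, ylim))
  o <- kOcc$z; e <- kBg$z
  o[o < 0] <- 0; e[e < 0] <- 0
  # Gaussian kernels have unbounded support; densities below tau * max are
  # numerical tail mass, not niche, and are treated as outside the support
  o[o < tau * max(o)] <- 0
  if (corrected) {
    z <- matrix(0, r, r)
    ok <- e > tau * max(e)
    z[ok] <- o[ok] / e[ok]
  } else {
    z <- o
    z[e <= 0] <- 0
  }
  s <- sum(z)
  if (s <= 0) stop("occupancy is zero everywhere on the grid")
  new("EnvSpaceGrid", species = species, xGrid = kOcc$x, yGrid = kOcc$y,
      occDensity = o, envDensity = e, z = z / s, corrected = corrected)
}

#' Schoener's D niche overlap
#'
#' `D = 1 - 0.5 * sum |z_A - z_B|` over the shared environmental grid;
#' 0 = disjoint niches, 1 = identical. Unnormalized inputs are normalized
#' with a warning.
#'
#' @param zA,zB occupancy grids: [EnvSpaceGrid-class] objects or bare
#'   non-negative matrices on the same grid.
#' @return D in [0, 1].
#' @export
schoenersD <- function(zA, zB) {
  a <- if (is(zA, "EnvSpaceGrid")) occupancy(zA) else as.matrix(zA)
  b <- if (is(zB, "EnvSpaceGrid")) occupancy(zB) else as.matrix(zB)
  if (!identical(dim(a), dim(b))) stop("occupancy grids differ in dimension")
  for (nm in c("a", "b")) {
    m <- get(nm)
    if (abs(sum(m) - 1) > 1e-9) {
      warning("unnormalized occupancy: normalizing to sum 1")
      assign(nm, m / sum(m))
    }
  }
  max(0, min(1, 1 - 0.5 * sum(abs(a - b))))
}

#' Density contours of an occupancy grid
#'
#' The q-contour is the smallest set of cells whose occupancy mass reaches
#' q (cells ranked by density); niche breadth is the cell count inside.
#'
#' @param z an [EnvSpaceGrid-class] or normalized occupancy matrix.
#' @param levels mass levels (default 0.5 and 1).
#' @return list per level: logical membership matrix with attribute
#'   `breadth` (cell count).
#' @export
nicheContours <- function(z, levels = c(0.5, 1)) {
  m <- if (is(z, "EnvSpaceGrid")) occupancy(z) else as.matrix(z)
  ord <- order(m, decreasing = TRUE)
  cs <- cumsum(m[ord])
  out <- lapply(levels, function(q) {
    k <- if (q >= 1) sum(m > 0) else which(cs >= q - 1e-12)[1L]
    memb <- matrix(FALSE, nrow(m), ncol(m))
    memb[ord[seq_len(k)]] <- TRUE
    attr(memb, "breadth") <- k
    memb
  })
  names(out) <- paste0("q", levels)
  out
}

#' Niche breadth at a mass level
#'
#' @inheritParams nicheContours
#' @param level mass level (default 1: all occupied cells).
#' @return cell count inside the contour.
#' @export
nicheBreadth <- function(z, level = 1) {
  attr(nicheContours(z, levels = level)[[1L]], "breadth")
}

#' One-dimensional niche overlap per variable
#'
#' Gaussian kernel densities of each species' occurrence values on a common
#' 512-point grid spanning the background range, with detected local maxima
#' (ordered primary first) and the per-variable Schoener's D of the two
#' normalized densities.
#'
#' @param valuesA,valuesB numeric occurrence values of one variable for each
#'   species (>= 5 each).
#' @param bgValues background values of the variable (sets the grid range).
#' @return list of class "VariableOverlap": `grid`, `densityA`, `densityB`,
#'   `peaksA`, `peaksB` (data.frames location/height), `D`.
#' @export
variableOverlap1d <- function(valuesA, valuesB, bgValues) {
  if (length(valuesA) < 5L || length(valuesB) < 5L)
    stop("need at least 5 values per species")
  rng <- range(bgValues)
  if (diff(rng) == 0) {
    warning("constant variable: degenerate density")
    rng <- rng + c(-0.5, 0.5)
  }
  dens <- function(v) stats::density(v, from = rng[1L], to = rng[2L],
                                     n = 512)$y
  grid <- seq(rng[1L], rng[2L], length.out = 512)
  dA <- dens(valuesA); dB <- dens(valuesB)
  peaks <- function(d) {
    i <- which(diff(sign(diff(d))) == -2) + 1L
    if (d[1L] > d[2L]) i <- c(1L, i)
    if (d[512L] > d[511L]) i <- c(i, 512L)
    i <- i[order(-d[i])]
    data.frame(location = grid[i], height = d[i])
  }
  zA <- dA / sum(dA); zB <- dB / sum(dB)
  structure(list(grid = grid, densityA = dA, densityB = dB,
                 peaksA = peaks(dA), peaksB = peaks(dB),
                 D = 1 - 0.5 * sum(abs(zA - zB))),
            class = "VariableOverlap")
}
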