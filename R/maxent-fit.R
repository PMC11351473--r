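#' Fit an L1-regularized maximum-entropy model
#'
#' Maximizes the penalized log-likelihood of the Gibbs distribution over
#' background cells,
#' \deqn{\frac1m \sum_{i \in presence} \lambda' f(x_i) - \log Z_\lambda
#'       - \sum_j \beta_j |\lambda_j|,}
#' with \eqn{Z_\lambda = \frac1n \sum_{background} e^{\lambda' f(x)}}, by
#' cyclic coordinate descent with soft-thresholded Newton steps and exact
#' objective checks (step halving on any decrease), so the regularized gain
#' is non-decreasing across updates. The gain of each accepted update is
#' recorded per feature for percent-contribution attribution.
#'
#' @param presenceDesign feature matrix of presences (rows) from
#'   [featureDesign()].
#' @param backgroundDesign feature matrix of background cells.
#' @param features the "FeatureSet" the designs came from.
#' @param betaMultiplier global multiplier on the per-feature L1 penalties
#'   (default 1).
#' @param tol convergence: stop when a full sweep improves the objective by
#'   less than this (default 1e-6).
#' @param maxIter maximum number of sweeps; non-convergence returns the best
#'   iterate with `converged = FALSE`, not an error.
#' @param seed stored in metadata (fitting itself is deterministic).
#' @return a [MaxEntModel-class].
#' @export
fitMaxent <- function(presenceDesign, backgroundDesign, features,
                      betaMultiplier = 1, tol = 1e-6, maxIter = 500,
                      seed = NA_integer_) {
  Fpr <- as.matrix(presenceDesign)
  Fbg <- as.matrix(backgroundDesign)
  m <- nrow(Fpr); n <- nrow(Fbg)
  if (m < 2L) stop("need at least 2 presence records")
  J <- ncol(Fbg)
  stopifnot(ncol(Fpr) == J, J == length(features$defs))

  # per-feature penalties: class constant x presence-sd / sqrt(m)
  classConst <- vapply(features$defs, function(d)
    switch(d$kind, linear = 1, quadratic = 1, product = 1, hinge = 1.5), 1)
  sdPr <- pmax(apply(Fpr, 2L, stats::sd), 0.05)
  beta <- betaMultiplier * classConst * sdPr / sqrt(m)

  meanFpr <- unname(colMeans(Fpr))
  lambda <- numeric(J)
  eta <- numeric(n)          # Fbg %*% lambda
  prTerm <- 0                # mean(Fpr %*% lambda)
  lse <- 0                   # log mean exp(eta)
  obj <- 0                   # objective at lambda = 0
  trace <- list()

  logMeanExp <- function(e) {
    mx <- max(e)
    mx + log(mean(exp(e - mx)))
  }

  converged <- FALSE
  for (sweep in seq_len(maxIter)) {
    objStart <- obj
    for (j in seq_len(J)) {
      fj <- Fbg[, j]
      w <- exp(eta - lse) / n          # q over background
      Eq <- sum(w * fj)
      g <- meanFpr[j] - Eq
      h <- max(sum(w * fj^2) - Eq^2, 1e-10)
      z <- lambda[j] + g / h
      lamNew <- sign(z) * max(0, abs(z) - beta[j] / h)
      if (lamNew == lambda[j]) next
      # exact objective with step halving to guarantee monotone gain
      accepted <- FALSE
      for (half in 0:8) {
        cand <- lambda[j] + (lamNew - lambda[j]) / 2^half
        delta <- cand - lambda[j]
        etaNew <- eta + delta * fj
        lseNew <- logMeanExp(etaNew)
        prNew <- prTerm + delta * meanFpr[j]
        objNew <- prNew - lseNew -
          sum(beta * abs(replace(lambda, j, cand)))
        if (objNew >= obj - 1e-12) {
          gainInc <- objNew - obj
          lambda[j] <- cand
          eta <- etaNew; lse <- lseNew; prTerm <- prNew; obj <- objNew
          if (gainInc > 0)
            trace[[length(trace) + 1L]] <- c(feature = j, gain = gainInc)
          accepted <- TRUE
          break
        }
      }
      if (!accepted) next
    }
    if (obj - objStart < tol) { converged <- TRUE; break }
  }

  w <- exp(eta - lse) / n
  H <- -sum(w * log(pmax(w, 1e-300)))
  gainTrace <- if (length(trace)) {
    tr <- do.call(rbind, trace)
    data.frame(feature = as.integer(tr[, "feature"]), gain = tr[, "gain"])
  } else data.frame(feature = integer(), gain = numeric())

  new("MaxEntModel",
      features = unclass(features),
      coefficients = lambda,
      beta = beta,
      logZ = lse + log(n),   # log sum over background of exp(eta)
      entropy = H,
      gainTrace = gainTrace,
      converged = converged,
      meta = list(n_presence = m, n_background = n, seed = seed,
                  betaMultiplier = betaMultiplier, gain = obj))
}

# linear predictor lambda' f(x) for covariate values, touching only
# non-zero coefficients (L1 keeps most at zero)
maxentEta <- function(model, values) {
  nz <- which(model@coefficients != 0)
  if (!length(nz)) return(rep(0, nrow(values)))
  fs <- structure(model@features, class = "FeatureSet")
  D <- featureDesign(fs, values, which = nz)
  as.vector(D %*% model@coefficients[nz])
}

#' Regularized training gain of a fitted model
#'
#' @param model a [MaxEntModel-class].
#' @return the regularized gain (objective value at the optimum).
#' @export
trainingGain <- function(model) model@meta$gain

#' Predict MaxEnt output over a stack
#'
#' `predictRaw` returns the Gibbs density renormalized over the prediction
#' cells (sums to 1 over valid cells); `predictLogistic` returns
#' \eqn{q e^H / (1 + q e^H)} in (0, 1), where q is normalized over the
#' training background, so an uninformative model scores 0.5 everywhere.
#' Nodata cells propagate.
#'
#' @param model a [MaxEntModel-class].
#' @param stack an [EnvStack-class] containing every source layer.
#' @param name output layer name.
#' @return a [RasterGrid-class].
#' @export
predictRaw <- function(model, stack, name = "raw") {
  vals <- stackValues(stack)
  checkModelLayers(model, vals)
  eta <- maxentEta(model, vals)
  mx <- max(eta)
  p <- exp(eta - mx); p <- p / sum(p)
  gridFromCells(stack, p, attr(vals, "cells"), name)
}

#' @rdname predictRaw
#' @export
predictLogistic <- function(model, stack, name = "logistic") {
  vals <- stackValues(stack)
  checkModelLayers(model, vals)
  eta <- maxentEta(model, vals)
  qeh <- exp(eta - model@logZ + model@entropy)
  logi <- qeh / (1 + qeh)
  gridFromCells(stack, logi, attr(vals, "cells"), name)
}

checkModelLayers <- function(model, vals) {
  miss <- setdiff(model@features$variables, colnames(vals))
  if (length(miss))
    stop(sprintf("stack is missing model layer(s): %s",
                 paste(miss, collapse = ", ")))
}

gridFromCells <- function(stack, values, cells, name) {
  ref <- stack@layers[[1L]]
  m <- matrix(NA_real_, nrow(ref@values), ncol(ref@values))
  m[cells] <- values
  rasterGrid(m, xOrigin = ref@xOrigin, yOrigin = ref@yOrigin,
             cellSize = ref@cellSize, nodata = ref@nodata, name = name)
}
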