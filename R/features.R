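#' Build a MaxEnt feature set from covariate values
#'
#' Derives feature definitions and their min-max scaling from a pool of
#' covariate values (presence + background rows only; never the whole map).
#' All features map to [0, 1]:
#' \itemize{
#'   \item linear: min-max scaled value;
#'   \item quadratic: squared scaled value;
#'   \item product: pairwise products of scaled values;
#'   \item hinge: forward `max(0, v - k) / (max - k)` and reverse
#'     `max(0, k - v) / (k - min)` at evenly spaced interior knots.
#' }
#' Features that are constant over the pool (e.g. hinges at the range
#' boundary, or any feature of a constant covariate) are pruned with a
#' warning.
#'
#' @param values numeric matrix of covariate values (rows = pool samples,
#'   named columns = variables).
#' @param classes feature classes to enable; subset of
#'   c("linear", "quadratic", "product", "hinge").
#' @param nHingeKnots number of interior knots per variable and direction.
#' @return list of class "FeatureSet": `defs` (list of feature definitions:
#'   kind, vars, knot, reverse), `scaling` (per-variable min/max),
#'   `variables` (column names).
#' @export
buildFeatures <- function(values, classes = c("linear", "quadratic"),
                          nHingeKnots = 8) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have named columns")
  vars <- colnames(values)
  lo <- apply(values, 2L, min)
  hi <- apply(values, 2L, max)
  const <- vars[hi - lo <= 0]
  if (length(const))
    warning(sprintf("constant covariate(s) %s: only a (degenerate) linear feature emitted",
                    paste(const, collapse = ", ")))
  defs <- list()
  addDef <- function(kind, v, knot = NA_real_, reverse = FALSE) {
    defs[[length(defs) + 1L]] <<- list(kind = kind, vars = v, knot = knot,
                                       reverse = reverse)
  }
  for (v in vars) addDef("linear", v)
  if ("quadratic" %in% classes)
    for (v in setdiff(vars, const)) addDef("quadratic", v)
  if ("product" %in% classes && length(setdiff(vars, const)) > 1L) {
    ok <- setdiff(vars, const)
    for (i in seq_along(ok)[-length(ok)])
      for (j in (i + 1L):length(ok)) addDef("product", c(ok[i], ok[j]))
  }
  if ("hinge" %in% classes) {
    for (v in setdiff(vars, const)) {
      knots <- seq(lo[v], hi[v], length.out = nHingeKnots + 2L)
      knots <- knots[-c(1L, nHingeKnots + 2L)]
      for (k in knots) {
        addDef("hinge", v, knot = k, reverse = FALSE)
        addDef("hinge", v, knot = k, reverse = TRUE)
      }
    }
  }
  fs <- structure(list(defs = defs,
                       scaling = list(min = lo, max = hi),
                       variables = vars),
                  class = "FeatureSet")
  # prune features degenerate on the pool
  design <- featureDesign(fs, values)
  keep <- apply(design, 2L, function(col) max(col) - min(col) > 1e-12)
  # always keep at least the linear features so the model has a column per variable
  keep[vapply(fs$defs, function(d) d$kind == "linear", TRUE)] <- TRUE
  fs$defs <- fs$defs[keep]
  fs
}

#' Evaluate a feature set on covariate values
#'
#' Values outside the training range are clamped to it, so features stay in
#' [0, 1] when predicting beyond the pool.
#'
#' @param features a "FeatureSet" from [buildFeatures()].
#' @param values covariate matrix with (at least) the feature set's columns.
#' @param which optional integer vector of feature indices to evaluate.
#' @return numeric matrix, one column per (selected) feature.
#' @export
featureDesign <- function(features, values, which = NULL) {
  values <- as.matrix(values)
  miss <- setdiff(features$variables, colnames(values))
  if (length(miss))
    stop(sprintf("values missing variable(s): %s", paste(miss, collapse = ", ")))
  lo <- features$scaling$min
  hi <- features$scaling$max
  rng <- pmax(hi - lo, 1e-300)
  scaled <- sweep(sweep(values[, features$variables, drop = FALSE], 2L, lo),
                  2L, rng, "/")
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  idx <- if (is.null(which)) seq_along(features$defs) else which
  out <- matrix(0, nrow(values), length(idx))
  for (k in seq_along(idx)) {
    d <- features$defs[[idx[k]]]
    out[, k] <- switch(d$kind,
      linear = scaled[, d$vars],
      quadratic = scaled[, d$vars]^2,
      product = scaled[, d$vars[1L]] * scaled[, d$vars[2L]],
      hinge = {
        v <- d$vars
        # knot in original units; work on the clamped original scale
        s <- scaled[, v] * (hi[v] - lo[v]) + lo[v]
        if (d$reverse) {
          den <- d$knot - lo[v]
          if (den <= 0) rep(0, nrow(values)) else pmax(0, d$knot - s) / den
        } else {
          den <- hi[v] - d$knot
          if (den <= 0) rep(0, nrow(values)) else pmax(0, s - d$knot) / den
        }
      },
      stop(sprintf("unknown feature kind '%s'", d$kind)))
  }
  colnames(out) <- vapply(features$defs[idx], featureLabel, "")
  out
}

featureLabel <- function(d) {
  switch(d$kind,
    linear = d$vars,
    quadratic = paste0(d$vars, "^2"),
    product = paste(d$vars, collapse = "*"),
    hinge = sprintf("%s%s@%.4g", if (d$reverse) "rev_hinge:" else "hinge:",
                    d$vars, d$knot))
}

#' Feature classes enabled by presence count
#'
#' Mirrors the common MaxEnt convention of enabling richer feature classes
#' as sample size grows: linear always; quadratic from 10 presences; hinge
#' from 15; product from 80.
#'
#' @param nPresence number of presence records.
#' @return character vector of class names.
#' @export
autoFeatureClasses <- function(nPresence) {
  cl <- "linear"
  if (nPresence >= 10) cl <- c(cl, "quadratic")
  if (nPresence >= 15) cl <- c(cl, "hinge")
  if (nPresence >= 80) cl <- c(cl, "product")
  cl
}
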