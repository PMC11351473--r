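#' Pairwise Pearson correlation of stack layers
#'
#' Computes the Pearson correlation matrix of the layers over a cell sample:
#' by default every joint-valid cell (the band-statistics convention), or the
#' cells containing a supplied set of background points. Constant layers get
#' undefined (NA) correlations and are flagged for automatic exclusion.
#'
#' @param stack an [EnvStack-class].
#' @param sample "all" (default: all joint-valid cells) or an
#'   [OccurrenceSet-class] of sampling points.
#' @return list of class "CorrelationReport": `r` (correlation matrix),
#'   `n` (cells used), `constant` (names of constant layers).
#' @export
pearsonMatrix <- function(stack, sample = "all") {
  vals <- if (is(sample, "OccurrenceSet")) {
    extractValues(stack, sample, quiet = TRUE)
  } else {
    stackValues(stack)
  }
  if (nrow(vals) < 3L) stop("need at least 3 joint-valid samples")
  sds <- apply(vals, 2L, stats::sd)
  constant <- colnames(vals)[sds == 0]
  if (length(constant))
    warning(sprintf("constant layer(s) %s: correlations undefined, will be dropped",
                    paste(constant, collapse = ", ")))
  r <- suppressWarnings(stats::cor(vals))
  structure(list(r = r, n = nrow(vals), constant = constant),
            class = "CorrelationReport")
}

#' Screen variables by pairwise correlation
#'
#' Greedy selection in priority order: a layer is retained iff its absolute
#' Pearson correlation with every already-retained layer is strictly below
#' the threshold. Returns a full provenance report of which partner forced
#' each drop.
#'
#' @param report a "CorrelationReport" from [pearsonMatrix()], or a bare
#'   correlation matrix.
#' @param threshold retain pairs with |r| < threshold (default 0.8).
#' @param priority optional ordered character vector of layer names; layers
#'   earlier in the list are considered first. Defaults to matrix order.
#' @return list of class "ScreeningResult": `retained` (ordered names),
#'   `dropped` (data.frame: layer, partner, r), `threshold`.
#' @export
screenVariables <- function(report, threshold = 0.8, priority = NULL) {
  r <- if (inherits(report, "CorrelationReport")) report$r else as.matrix(report)
  constant <- if (inherits(report, "CorrelationReport")) report$constant else character()
  vars <- colnames(r)
  if (is.null(priority)) priority <- vars
  miss <- setdiff(vars, priority)
  if (length(miss))
    stop(sprintf("priority list missing layer(s): %s", paste(miss, collapse = ", ")))
  unknown <- setdiff(priority, vars)
  if (length(unknown))
    stop(sprintf("priority names not in matrix: %s", paste(unknown, collapse = ", ")))
  retained <- character()
  dropped <- data.frame(layer = character(), partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  for (v in priority) {
    if (v %in% constant) {
      dropped <- rbind(dropped, data.frame(layer = v, partner = NA_character_,
                                           r = NA_real_))
      next
    }
    conflict <- retained[abs(r[v, retained]) >= threshold]
    if (length(conflict)) {
      worst <- conflict[which.max(abs(r[v, conflict]))]
      dropped <- rbind(dropped, data.frame(layer = v, partner = worst,
                                           r = r[v, worst]))
    } else {
      retained <- c(retained, v)
    }
  }
  # post-hoc assertion of the pairwise constraint
  if (length(retained) > 1L) {
    sub <- abs(r[retained, retained])
    diag(sub) <- 0
    stopifnot(all(sub < threshold))
  }
  structure(list(retained = retained, dropped = dropped, threshold = threshold),
            class = "ScreeningResult")
}
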