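#' @import methods
NULL

#' Single-layer raster grid
#'
#' Carrier for one environmental covariate on a regular grid of square cells.
#' Values are stored as a matrix whose first row is the northernmost row;
#' the origin is the lower-left corner of the grid, following the ESRI ASCII
#' grid convention. Cells are half-open `[x, x+cs) x [y, y+cs)` so a point on
#' a shared edge belongs to the cell whose lower/left edge it touches.
#'
#' @slot values numeric matrix of cell values (row 1 = north).
#' @slot xOrigin,yOrigin lower-left corner, projected metres.
#' @slot cellSize cell edge length in metres.
#' @slot nodata sentinel value marking invalid cells.
#' @slot name layer label.
#' @export
setClass("RasterGrid",
  representation(
    values = "matrix",
    xOrigin = "numeric",
    yOrigin = "numeric",
    cellSize = "numeric",
    nodata = "numeric",
    name = "character"
  )
)

setValidity("RasterGrid", function(object) {
  msgs <- character()
  if (!is.numeric(object@values)) msgs <- c(msgs, "values must be numeric")
  if (length(object@cellSize) != 1L || object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@xOrigin) != 1L || length(object@yOrigin) != 1L)
    msgs <- c(msgs, "origin must be scalar x and y")
  if (length(object@nodata) != 1L) msgs <- c(msgs, "nodata must be scalar")
  if (length(object@name) != 1L || !nzchar(object@name))
    msgs <- c(msgs, "name must be a non-empty string")
  v <- object@values
  if (any(!is.finite(v) & !is.na(v)))
    msgs <- c(msgs, "values must be finite, NA, or the nodata sentinel")
  if (length(msgs)) msgs else TRUE
})

#' Co-registered stack of raster layers
#'
#' Ordered, uniquely named set of [RasterGrid-class] layers sharing
#' dimensions, origin and cell size. Nodata masks are unified at
#' construction: a cell that is nodata in any layer is nodata in all.
#'
#' @slot layers named list of RasterGrid objects.
#' @export
setClass("EnvStack", representation(layers = "list"))

setValidity("EnvStack", function(object) {
  ll <- object@layers
  if (length(ll) == 0L) return("stack must contain at least one layer")
  if (!all(vapply(ll, is, TRUE, "RasterGrid")))
    return("all layers must be RasterGrid objects")
  nm <- names(ll)
  if (is.null(nm) || any(!nzchar(nm))) return("layers must be named")
  if (anyDuplicated(nm)) return("layer names must be unique")
  ref <- ll[[1L]]
  for (g in ll) {
    if (!identical(dim(g@values), dim(ref@values)))
      return("layers differ in dimensions")
    if (g@xOrigin != ref@xOrigin || g@yOrigin != ref@yOrigin)
      return("layers differ in origin")
    if (g@cellSize != ref@cellSize) return("layers differ in cell size")
  }
  TRUE
})

#' Species occurrence points
#'
#' Presence (or background) locations for one species, in projected metre
#' coordinates, each tagged with a data source.
#'
#' @slot species species label.
#' @slot points data.frame with numeric columns `x`, `y` and character
#'   column `source`; extra columns are preserved.
#' @export
setClass("OccurrenceSet",
  representation(species = "character", points = "data.frame")
)

setValidity("OccurrenceSet", function(object) {
  if (length(object@species) != 1L || !nzchar(object@species))
    return("species must be a non-empty string")
  p <- object@points
  need <- c("x", "y", "source")
  if (!all(need %in% names(p)))
    return(sprintf("points must have columns %s", paste(need, collapse = ", ")))
  if (nrow(p) && (!is.numeric(p$x) || !is.numeric(p$y)))
    return("coordinates must be numeric")
  if (nrow(p) && any(!is.finite(p$x) | !is.finite(p$y)))
    return("coordinates must be finite")
  TRUE
})

#' Fitted maximum-entropy habitat model
#'
#' The Gibbs distribution q(x) = exp(sum_j lambda_j f_j(x)) / Z over the
#' background cells, with its feature definitions, L1 penalties, log
#' normalizer and entropy. Logistic output is q * e^H / (1 + q * e^H).
#'
#' @slot features feature set from [buildFeatures()].
#' @slot coefficients numeric vector lambda, one per feature.
#' @slot beta per-feature L1 penalty.
#' @slot logZ log normalizer over background (q sums to 1 over background).
#' @slot entropy entropy H of the fitted background distribution.
#' @slot gainTrace data.frame of per-update gain increments (feature,
#'   variables, gain), used for percent-contribution attribution.
#' @slot converged logical convergence flag.
#' @slot meta list of training metadata (n_presence, n_background, seed, ...).
#' @export
setClass("MaxEntModel",
  representation(
    features = "list",
    coefficients = "numeric",
    beta = "numeric",
    logZ = "numeric",
    entropy = "numeric",
    gainTrace = "data.frame",
    converged = "logical",
    meta = "list"
  )
)

setValidity("MaxEntModel", function(object) {
  J <- length(object@features$defs)
  if (length(object@coefficients) != J) return("one coefficient per feature required")
  if (length(object@beta) != J) return("one penalty per feature required")
  if (length(object@entropy) != 1L || object@entropy < -1e-8)
    return("entropy must be a non-negative scalar")
  TRUE
})

#' Gridded occupancy in two-dimensional environmental space
#'
#' An r x r grid over the first two principal components, holding the
#' kernel-smoothed occurrence density `occDensity`, the availability
#' (background) density `envDensity`, and the occupancy `z` (optionally
#' corrected by availability), normalized to sum to 1.
#'
#' @slot species species label.
#' @slot xGrid,yGrid cell-centre coordinates on Dim1/Dim2.
#' @slot occDensity,envDensity,z numeric r x r matrices.
#' @slot corrected logical; TRUE if z is occurrence density divided by
#'   availability.
#' @export
setClass("EnvSpaceGrid",
  representation(
    species = "character",
    xGrid = "numeric",
    yGrid = "numeric",
    occDensity = "matrix",
    envDensity = "matrix",
    z = "matrix",
    corrected = "logical"
  )
)

setValidity("EnvSpaceGrid", function(object) {
  d <- c(length(object@xGrid), length(object@yGrid))
  for (nm in c("occDensity", "envDensity", "z")) {
    m <- slot(object, nm)
    if (!identical(dim(m), as.integer(d)))
      return(sprintf("%s dimensions must match the grid axes", nm))
    if (any(m < -1e-12)) return(sprintf("%s must be non-negative", nm))
  }
  if (abs(sum(object@z) - 1) > 1e-9) return("z must sum to 1")
  if (any(object@z[object@envDensity == 0] > 0))
    return("z must vanish where availability is zero")
  TRUE
})
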