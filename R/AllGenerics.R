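#' Accessors for raster and occurrence objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(x, ...) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setGeneric("layerNames", function(x, ...) standardGeneric("layerNames"))

#' @rdname accessors
#' @export
setGeneric("nLayers", function(x, ...) standardGeneric("nLayers"))

#' @rdname accessors
#' @export
setGeneric("cellSize", function(x, ...) standardGeneric("cellSize"))

#' @rdname accessors
#' @export
setGeneric("gridDim", function(x, ...) standardGeneric("gridDim"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x, ...) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, name, ...) standardGeneric("getLayer"))

#' @rdname accessors
#' @export
setGeneric("speciesName", function(x, ...) standardGeneric("speciesName"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(x, ...) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

## -- RasterGrid ------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x, ...) {
  v <- x@values
  v[v == x@nodata] <- NA_real_
  v
})

#' @rdname accessors
#' @export
setMethod("cellSize", "RasterGrid", function(x, ...) x@cellSize)

#' @rdname accessors
#' @export
setMethod("gridDim", "RasterGrid", function(x, ...) dim(x@values))

#' @rdname accessors
#' @export
setMethod("validMask", "RasterGrid", function(x, ...) {
  !is.na(x@values) & x@values != x@nodata
})

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  nv <- sum(validMask(object))
  cat(sprintf("RasterGrid '%s': %d x %d cells of %g m (%d valid)\n",
              object@name, d[1], d[2], object@cellSize, nv))
  cat(sprintf("  origin (%g, %g), nodata %g\n",
              object@xOrigin, object@yOrigin, object@nodata))
})

## -- EnvStack ---------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("layerNames", "EnvStack", function(x, ...) names(x@layers))

#' @rdname accessors
#' @export
setMethod("nLayers", "EnvStack", function(x, ...) length(x@layers))

#' @rdname accessors
#' @export
setMethod("cellSize", "EnvStack", function(x, ...) x@layers[[1L]]@cellSize)

#' @rdname accessors
#' @export
setMethod("gridDim", "EnvStack", function(x, ...) dim(x@layers[[1L]]@values))

#' @rdname accessors
#' @export
setMethod("getLayer", "EnvStack", function(x, name, ...) {
  if (!name %in% names(x@layers))
    stop(sprintf("layer '%s' not in stack (have: %s)", name,
                 paste(names(x@layers), collapse = ", ")))
  x@layers[[name]]
})

#' @rdname accessors
#' @export
setMethod("validMask", "EnvStack", function(x, ...) {
  m <- validMask(x@layers[[1L]])
  for (g in x@layers[-1L]) m <- m & validMask(g)
  m
})

setMethod("show", "EnvStack", function(object) {
  d <- gridDim(object)
  cat(sprintf("EnvStack: %d layers, %d x %d cells of %g m\n",
              nLayers(object), d[1], d[2], cellSize(object)))
  cat("  layers:", paste(layerNames(object), collapse = ", "), "\n")
})

## -- OccurrenceSet ----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("speciesName", "OccurrenceSet", function(x, ...) x@species)

#' @rdname accessors
#' @export
setMethod("coords", "OccurrenceSet", function(x, ...) {
  cbind(x = x@points$x, y = x@points$y)
})

#' @rdname accessors
#' @export
setMethod("nPoints", "OccurrenceSet", function(x, ...) nrow(x@points))

setMethod("show", "OccurrenceSet", function(object) {
  src <- table(object@points$source)
  cat(sprintf("OccurrenceSet '%s': %d points (%s)\n", object@species,
              nrow(object@points),
              paste(sprintf("%s: %d", names(src), src), collapse = ", ")))
})

## -- MaxEntModel ------------------------------------------------------------

setMethod("show", "MaxEntModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat(sprintf("MaxEntModel: %d features (%d active), entropy %.4f%s\n",
              length(object@coefficients), nz, object@entropy,
              if (object@converged) "" else " [not converged]"))
  cat(sprintf("  trained on %d presences vs %d background\n",
              object@meta$n_presence, object@meta$n_background))
})

## -- EnvSpaceGrid -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("occupancy", "EnvSpaceGrid", function(x, ...) x@z)

#' @rdname accessors
#' @export
setMethod("speciesName", "EnvSpaceGrid", function(x, ...) x@species)

setMethod("show", "EnvSpaceGrid", function(object) {
  cat(sprintf(
    "EnvSpaceGrid '%s': %d x %d cells, %s occupancy, %d cells occupied\n",
    object@species, length(object@xGrid), length(object@yGrid),
    if (object@corrected) "availability-corrected" else "uncorrected",
    sum(object@z > 0)))
})
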