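#' Thin occurrences to one record per grid cell
#'
#' Removes spatial duplicates: at most one record per species per grid cell,
#' mitigating spatial autocorrelation before habitat modelling. The thinning
#' grid is anchored at the reference raster's origin (not the data bounding
#' box) so results do not depend on point order or extent, and the first
#' record in input order is the one retained (deterministic).
#'
#' @param occ an [OccurrenceSet-class].
#' @param grid a [RasterGrid-class] or [EnvStack-class] supplying the grid
#'   origin.
#' @param cellSize thinning cell edge in metres (default 30).
#' @param quiet suppress the removed-count message.
#' @return an [OccurrenceSet-class]; attribute `removed` gives the count of
#'   dropped duplicates.
#' @export
thinOccurrences <- function(occ, grid, cellSize = 30, quiet = FALSE) {
  if (is(grid, "EnvStack")) grid <- grid@layers[[1L]]
  p <- occ@points
  if (nrow(p) == 0L) {
    out <- occ
    attr(out, "removed") <- 0L
    return(out)
  }
  col <- floor((p$x - grid@xOrigin) / cellSize)
  row <- floor((p$y - grid@yOrigin) / cellSize)
  key <- paste(row, col, sep = "_")
  keep <- !duplicated(key)
  out <- new("OccurrenceSet", species = occ@species,
             points = p[keep, , drop = FALSE])
  removed <- sum(!keep)
  if (removed > 0 && !quiet)
    logMsg("thinOccurrences [%s]: removed %d duplicate record(s), %d retained",
           occ@species, removed, sum(keep))
  attr(out, "removed") <- removed
  out
}
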