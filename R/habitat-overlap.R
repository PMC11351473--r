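#' Binarize a suitability map at a threshold
#'
#' Cells with mean logistic suitability >= theta become suitable (1), below
#' become unsuitable (0); nodata is preserved. The boundary is inclusive
#' (a cell exactly at theta is suitable).
#'
#' @param map suitability [RasterGrid-class] (values in (0,1)).
#' @param theta threshold in (0, 1).
#' @return a [RasterGrid-class] with values in \{0, 1, nodata\}; attribute
#'   `theta` records the threshold.
#' @export
binarizeHabitat <- function(map, theta) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  v <- gridValues(map)
  b <- ifelse(is.na(v), NA_real_, as.numeric(v >= theta))
  out <- rasterGrid(b, xOrigin = map@xOrigin, yOrigin = map@yOrigin,
                    cellSize = map@cellSize, nodata = map@nodata,
                    name = paste0(map@name, "_binary"))
  attr(out, "theta") <- theta
  out
}

#' Suitable area in square kilometres
#'
#' Suitable-cell count times cell area (cell_size^2 / 1e6; a 30 m cell is
#' 0.0009 km2).
#'
#' @param map a binary habitat [RasterGrid-class] (values 0/1/nodata).
#' @return area in km2.
#' @export
areaKm2 <- function(map) {
  v <- gridValues(map)
  sum(v == 1, na.rm = TRUE) * map@cellSize^2 / 1e6
}

#' Area fraction as a percentage
#'
#' @param area,total areas in the same units; `total` must be positive.
#' @return 100 * area / total.
#' @export
areaFraction <- function(area, total) {
  if (total <= 0) stop("total area must be positive")
  100 * area / total
}

#' Habitat overlap statistics for two species
#'
#' Areas of each suitable habitat, their intersection, each as a fraction of
#' the study area, and the intersection as a share of each species' habitat.
#' Raw values are reported alongside values rounded to the reporting
#' precision (areas 2 dp, percentages: study-area fractions 2 dp,
#' intersection shares 1 dp).
#'
#' @param mapA,mapB co-registered binary habitat maps.
#' @param totalArea total study area in km2; defaults to the valid-cell area
#'   of `mapA`.
#' @return list of class "OverlapReport".
#' @export
overlapStats <- function(mapA, mapB, totalArea = NULL) {
  if (!identical(dim(mapA@values), dim(mapB@values)) ||
      mapA@xOrigin != mapB@xOrigin || mapA@yOrigin != mapB@yOrigin ||
      mapA@cellSize != mapB@cellSize)
    stop("maps are not co-registered (geotransform mismatch)")
  vA <- gridValues(mapA); vB <- gridValues(mapB)
  cellArea <- mapA@cellSize^2 / 1e6
  if (is.null(totalArea)) totalArea <- sum(!is.na(vA)) * cellArea
  areaA <- sum(vA == 1, na.rm = TRUE) * cellArea
  areaB <- sum(vB == 1, na.rm = TRUE) * cellArea
  inter <- sum(vA == 1 & vB == 1, na.rm = TRUE) * cellArea
  rep <- list(
    area_A = areaA, area_B = areaB, area_intersection = inter,
    total_area = totalArea,
    fraction_of_total_A = areaFraction(areaA, totalArea),
    fraction_of_total_B = areaFraction(areaB, totalArea),
    fraction_of_A = if (areaA > 0) areaFraction(inter, areaA) else 0,
    fraction_of_B = if (areaB > 0) areaFraction(inter, areaB) else 0
  )
  rep$rounded <- list(
    area_A = round(areaA, 2), area_B = round(areaB, 2),
    area_intersection = round(inter, 2),
    fraction_of_total_A = round(rep$fraction_of_total_A, 2),
    fraction_of_total_B = round(rep$fraction_of_total_B, 2),
    fraction_of_A = round(rep$fraction_of_A, 1),
    fraction_of_B = round(rep$fraction_of_B, 1)
  )
  structure(rep, class = "OverlapReport")
}

#' Combined categorical habitat map
#'
#' 0 = neither species, 1 = A only, 2 = B only, 3 = both.
#'
#' @param mapA,mapB co-registered binary habitat maps.
#' @return a [RasterGrid-class].
#' @export
combinedHabitatMap <- function(mapA, mapB) {
  vA <- gridValues(mapA); vB <- gridValues(mapB)
  m <- vA + 2 * vB
  m[vA == 1 & vB == 1] <- 3
  rasterGrid(m, xOrigin = mapA@xOrigin, yOrigin = mapA@yOrigin,
             cellSize = mapA@cellSize, nodata = mapA@nodata,
             name = "habitat_classes")
}
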