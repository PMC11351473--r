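#' Construct a RasterGrid
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xOrigin,yOrigin lower-left corner in projected metres.
#' @param cellSize cell edge in metres (default 30, the thinning-grid cell).
#' @param nodata nodata sentinel (default -9999).
#' @param name layer label.
#' @return a [RasterGrid-class] object. `NA` values are stored as the
#'   nodata sentinel.
#' @export
rasterGrid <- function(values, xOrigin = 0, yOrigin = 0, cellSize = 30,
                       nodata = -9999, name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  values[is.na(values)] <- nodata
  new("RasterGrid", values = values, xOrigin = xOrigin, yOrigin = yOrigin,
      cellSize = cellSize, nodata = nodata, name = name)
}

#' Construct an EnvStack from RasterGrid layers
#'
#' Layers must be co-registered. The nodata mask is unified: a cell invalid
#' in any layer becomes nodata in every layer.
#'
#' @param ... RasterGrid objects, or a single (named) list of them.
#' @return an [EnvStack-class].
#' @export
envStack <- function(...) {
  ll <- list(...)
  if (length(ll) == 1L && is.list(ll[[1L]]) && !is(ll[[1L]], "RasterGrid"))
    ll <- ll[[1L]]
  if (is.null(names(ll)) || any(!nzchar(names(ll))))
    names(ll) <- vapply(ll, function(g) g@name, "")
  # unify nodata masks across layers
  mask <- Reduce(`&`, lapply(ll, validMask))
  ll <- lapply(ll, function(g) {
    v <- g@values
    v[!mask] <- g@nodata
    g@values <- v
    g
  })
  new("EnvStack", layers = ll)
}

## -- ESRI ASCII grid ---------------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Parses the NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_VALUE header
#' (case-insensitive; NODATA_VALUE optional, default -9999) followed by
#' row-major values, northern row first.
#'
#' @param path file path.
#' @param name layer label; defaults to the file name without extension.
#' @return a [RasterGrid-class].
#' @export
readAsciiGrid <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(parts[1L])]] <- as.numeric(parts[2L])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop(sprintf("malformed ASCII grid header in %s: missing %s",
                 path, paste(toupper(miss), collapse = ", ")))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  body <- paste(lines[i:length(lines)], collapse = "\n")
  vals <- scan(text = body, what = double(), quiet = TRUE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr)
    stop(sprintf(
      "ASCII grid body has %d values but header declares %d x %d = %d",
      length(vals), nr, nc, nr * nc))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  rasterGrid(m, xOrigin = hdr$xllcorner, yOrigin = hdr$yllcorner,
             cellSize = hdr$cellsize, nodata = nodata, name = name)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a [RasterGrid-class].
#' @param path output path.
#' @param digits significant digits for values (default 17: enough to make
#'   write-read round-trips bit-exact for doubles).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(grid, path, digits = 17) {
  d <- dim(grid@values)
  hdr <- c(
    sprintf("NCOLS %d", d[2]),
    sprintf("NROWS %d", d[1]),
    sprintf("XLLCORNER %.10g", grid@xOrigin),
    sprintf("YLLCORNER %.10g", grid@yOrigin),
    sprintf("CELLSIZE %.10g", grid@cellSize),
    sprintf("NODATA_VALUE %.10g", grid@nodata)
  )
  rows <- apply(grid@values, 1L, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write / read an EnvStack with a JSON manifest
#'
#' Each layer is written as `<name>.asc` next to a manifest mapping layer
#' names to files and recording the shared geotransform.
#'
#' @param stack an [EnvStack-class].
#' @param dir output directory (created if needed).
#' @param manifest manifest file name.
#' @return path of the manifest, invisibly.
#' @export
writeStack <- function(stack, dir, manifest = "stack.json") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in layerNames(stack)) {
    f <- paste0(nm, ".asc")
    writeAsciiGrid(getLayer(stack, nm), file.path(dir, f))
    files[nm] <- f
  }
  ref <- stack@layers[[1L]]
  man <- list(layers = as.list(files), cell_size = ref@cellSize,
              x_origin = ref@xOrigin, y_origin = ref@yOrigin,
              n_rows = nrow(ref@values), n_cols = ncol(ref@values))
  mp <- file.path(dir, manifest)
  jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname writeStack
#' @param path manifest path for reading.
#' @export
readStack <- function(path) {
  man <- jsonlite::read_json(path)
  dir <- dirname(path)
  ll <- lapply(names(man$layers), function(nm)
    readAsciiGrid(file.path(dir, man$layers[[nm]]), name = nm))
  names(ll) <- names(man$layers)
  envStack(ll)
}

## -- cell/coordinate transforms ----------------------------------------------

#' Map point coordinates to cell row/column indices
#'
#' Cells are half-open: a point on a cell's lower/left edge belongs to that
#' cell. Row 1 is the northernmost row. Points outside the extent get NA.
#'
#' @param grid a [RasterGrid-class] (or [EnvStack-class]) giving the
#'   geotransform.
#' @param x,y point coordinates in metres.
#' @return integer matrix with columns `row`, `col` (NA outside the extent).
#' @export
cellIndex <- function(grid, x, y) {
  if (is(grid, "EnvStack")) grid <- grid@layers[[1L]]
  d <- dim(grid@values)
  cs <- grid@cellSize
  col <- floor((x - grid@xOrigin) / cs) + 1
  rowFromBottom <- floor((y - grid@yOrigin) / cs) + 1
  row <- d[1] - rowFromBottom + 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Cell-centre coordinates of given row/column indices
#'
#' Inverse of [cellIndex()] on cell centres.
#'
#' @param grid geotransform source.
#' @param row,col cell indices (row 1 = north).
#' @return matrix with columns `x`, `y` (cell centres, metres).
#' @export
cellCenter <- function(grid, row, col) {
  if (is(grid, "EnvStack")) grid <- grid@layers[[1L]]
  d <- dim(grid@values)
  cs <- grid@cellSize
  x <- grid@xOrigin + (col - 0.5) * cs
  y <- grid@yOrigin + (d[1] - row + 0.5) * cs
  cbind(x = x, y = y)
}

#' Extract layer values at point locations
#'
#' Values come from the containing cell (no interpolation). Points outside
#' the extent or on a nodata cell are excluded; their count is reported via
#' a message and in the `excluded` attribute.
#'
#' @param stack an [EnvStack-class].
#' @param points an [OccurrenceSet-class] or a two-column matrix/data.frame
#'   of x, y coordinates.
#' @param quiet suppress the exclusion message.
#' @return numeric matrix, one row per retained point, one column per layer
#'   (stack order); attributes `kept` (row indices into the input) and
#'   `excluded` (count dropped).
#' @export
extractValues <- function(stack, points, quiet = FALSE) {
  if (is(points, "OccurrenceSet")) points <- coords(points)
  points <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(points) == 0L)
    stop("no points supplied")
  idx <- cellIndex(stack, points[, 1L], points[, 2L])
  mask <- validMask(stack)
  inGrid <- !is.na(idx[, 1L])
  lin <- rep(NA_integer_, nrow(points))
  lin[inGrid] <- (idx[inGrid, 2L] - 1L) * nrow(mask) + idx[inGrid, 1L]
  ok <- inGrid
  ok[inGrid] <- mask[lin[inGrid]]
  if (!any(ok)) stop("all points fall outside the valid extent")
  nExcl <- sum(!ok)
  if (nExcl > 0 && !quiet)
    message(sprintf("extractValues: excluded %d point(s) on nodata or outside extent", nExcl))
  out <- vapply(stack@layers, function(g) g@values[lin[ok]],
                numeric(sum(ok)))
  out <- matrix(out, nrow = sum(ok),
                dimnames = list(NULL, layerNames(stack)))
  attr(out, "kept") <- which(ok)
  attr(out, "excluded") <- nExcl
  out
}

#' Matrix of layer values over all valid cells
#'
#' @param stack an [EnvStack-class].
#' @return numeric matrix: one row per valid cell (column-major cell order),
#'   one column per layer; attribute `cells` holds the linear cell indices.
#' @export
stackValues <- function(stack) {
  mask <- validMask(stack)
  keep <- which(mask)
  out <- vapply(stack@layers, function(g) g@values[keep], numeric(length(keep)))
  out <- matrix(out, nrow = length(keep),
                dimnames = list(NULL, layerNames(stack)))
  attr(out, "cells") <- keep
  out
}
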