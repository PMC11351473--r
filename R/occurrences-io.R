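#' Construct an OccurrenceSet
#'
#' @param species species label.
#' @param x,y coordinates in projected metres.
#' @param source source tag per point (recycled), one of the survey/record
#'   types, e.g. "transect", "camera", "background", "synthetic".
#' @param extra optional data.frame of extra columns carried along.
#' @return an [OccurrenceSet-class].
#' @export
occurrenceSet <- function(species, x, y, source = "synthetic", extra = NULL) {
  n <- length(x)
  p <- data.frame(x = as.numeric(x), y = as.numeric(y),
                  source = rep_len(as.character(source), n),
                  stringsAsFactors = FALSE)
  if (!is.null(extra)) p <- cbind(p, extra)
  new("OccurrenceSet", species = species, points = p)
}

#' Read occurrence CSV
#'
#' Expects a header containing `species,x,y,source`; extra columns are
#' preserved. Returns one OccurrenceSet per species, in order of first
#' appearance.
#'
#' @param path CSV path.
#' @return named list of [OccurrenceSet-class] objects.
#' @export
readOccurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "source")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("occurrence CSV missing column(s) %s; found: %s",
                 paste(miss, collapse = ", "), paste(names(df), collapse = ", ")))
  for (cc in c("x", "y")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "")
    if (length(bad))
      stop(sprintf("non-numeric %s coordinate at data row %d ('%s')",
                   cc, bad[1L], df[[cc]][bad[1L]]))
    df[[cc]] <- v
  }
  if (nrow(df) == 0L) return(list())
  sp <- unique(df$species)
  out <- lapply(sp, function(s) {
    sub <- df[df$species == s, , drop = FALSE]
    extra <- sub[, setdiff(names(sub), need), drop = FALSE]
    occurrenceSet(s, sub$x, sub$y, sub$source,
                  extra = if (ncol(extra)) extra else NULL)
  })
  names(out) <- sp
  out
}

#' Write occurrences to CSV
#'
#' @param occ an [OccurrenceSet-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  if (is(occ, "OccurrenceSet")) occ <- list(occ)
  dfs <- lapply(occ, function(o)
    cbind(species = o@species, o@points, stringsAsFactors = FALSE))
  allNames <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (nm in setdiff(allNames, names(d))) d[[nm]] <- NA
    d[, allNames, drop = FALSE]
  })
  df <- do.call(rbind, dfs)
  front <- c("species", "x", "y", "source")
  df <- df[, c(front, setdiff(allNames, front)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
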