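## Occurrence data: CSV (species, lon, lat) in and out, with deduplication
## at grid-cell resolution ("spatially unique" localities).  Modelling
## operates on cells, so two records falling in the same cell carry no
## extra information and are collapsed to one.

#' Construct an occurrence set
#'
#' @param species species label.
#' @param cells column-major indices of occupied grid cells (unique).
#' @param spec the \code{\link{grid_spec}} the cells refer to.
#' @return an object of class \code{"occurrence_set"}; \code{points} holds
#'   the cell-center (lon, lat) coordinates.
#' @export
occurrence_set <- function(species, cells, spec) {
  if (!nzchar(species)) abort("empty species label")
  cells <- as.integer(cells)
  if (anyDuplicated(cells)) abort("duplicate cells in occurrence set")
  structure(list(species = species, cells = cells,
                 points = cell_center(cells, spec), spec = spec),
            class = "occurrence_set")
}

#' Read occurrences from CSV and snap them to a grid
#'
#' Expects columns \code{species}, \code{lon}, \code{lat}.  Points are
#' snapped to grid cells with the half-open convention of
#' \code{\link{point_to_cell}}; per species, points sharing a cell are
#' collapsed to one.  Any point outside the grid extent is an error.
#'
#' @param path CSV path.
#' @param spec a \code{\link{grid_spec}} defining the study grid.
#' @return named list of \code{\link{occurrence_set}} objects, one per
#'   species, in order of first appearance.  Per-species retained counts are
#'   attached as attribute \code{"n_unique"}.
#' @export
read_occurrences <- function(path, spec) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat")
  if (!all(need %in% names(df)))
    abort(path, ": occurrence CSV must have columns ",
          paste(need, collapse = ", "))
  if (nrow(df) == 0) abort(path, ": no occurrence rows")
  if (any(!nzchar(trimws(df$species))) || anyNA(df$species))
    abort(path, ": empty species label in rows ",
          paste(which(!nzchar(trimws(df$species)) | is.na(df$species)),
                collapse = ", "))
  cells <- point_to_cell(df$lon, df$lat, spec)
  if (anyNA(cells))
    abort(path, ": points outside the grid extent at rows ",
          paste(which(is.na(cells)), collapse = ", "))
  out <- list()
  for (sp in unique(df$species)) {
    cl <- unique(cells[df$species == sp])
    out[[sp]] <- occurrence_set(sp, cl, spec)
  }
  attr(out, "n_unique") <- vapply(out, function(o) length(o$cells), integer(1))
  out
}

#' Write occurrence sets to CSV
#'
#' @param occurrences list of \code{\link{occurrence_set}} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_occurrences <- function(occurrences, path) {
  df <- do.call(rbind, lapply(occurrences, function(o)
    data.frame(species = o$species, lon = o$points[, "lon"],
               lat = o$points[, "lat"])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d spatially unique points\n",
              x$species, length(x$cells)))
  invisible(x)
}
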