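## Grid geometry and in-memory raster containers.
##
## Rasters are stored north-to-south: row 1 of the value matrix is the
## northernmost row, matching the ESRI ASCII grid convention.  All cell
## indexing below is against this layout; cells are addressed either as
## (row, col) or as a single column-major index into the value matrix.

#' Grid geometry specification
#'
#' Describes the geometry of a regular lon/lat grid: dimensions, cell size
#' and the lower-left corner of the lower-left cell.  Two rasters are
#' co-registered when all five geometry fields agree.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param cell_size cell edge length in degrees.
#' @param x_ll,y_ll coordinates (degrees) of the lower-left corner of the
#'   lower-left (south-west) cell.
#' @param nodata sentinel value marking invalid cells.
#' @return an object of class \code{"grid_spec"}.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size, x_ll = 0, y_ll = 0,
                      nodata = -9999) {
  if (n_rows < 1 || n_cols < 1) abort("grid dimensions must be >= 1")
  if (cell_size <= 0) abort("cell_size must be > 0")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 x_ll = as.numeric(x_ll), y_ll = as.numeric(y_ll),
                 nodata = as.numeric(nodata)),
            class = "grid_spec")
}

#' Test whether two grid specifications are co-registered
#'
#' @param a,b \code{grid_spec} objects.
#' @param tol relative tolerance for the floating-point fields.
#' @return logical.
#' @export
same_grid <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size, tolerance = tol)) &&
    isTRUE(all.equal(a$x_ll, b$x_ll, tolerance = tol, scale = 1)) &&
    isTRUE(all.equal(a$y_ll, b$y_ll, tolerance = tol, scale = 1)) &&
    isTRUE(all.equal(a$nodata, b$nodata, tolerance = tol, scale = 1))
}

#' Construct a raster layer
#'
#' @param values numeric matrix, \code{n_rows x n_cols}, row 1 = northernmost
#'   row.  Cells equal to \code{spec$nodata} (or non-finite) are invalid.
#' @param spec a \code{\link{grid_spec}}.
#' @param name variable label (e.g. \code{"bio03"}).
#' @return an object of class \code{"enm_raster"}.
#' @export
enm_raster <- function(values, spec, name = "layer") {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (nrow(values) != spec$n_rows || ncol(values) != spec$n_cols)
    abort("value matrix is ", nrow(values), "x", ncol(values),
          " but grid_spec declares ", spec$n_rows, "x", spec$n_cols)
  storage.mode(values) <- "double"
  structure(list(values = values, spec = spec, name = name),
            class = "enm_raster")
}

#' Logical validity mask of a raster
#'
#' A cell is valid when its value is finite and differs from the nodata
#' sentinel.
#'
#' @param x an \code{enm_raster}.
#' @return logical matrix of the raster's shape.
#' @export
valid_mask <- function(x) {
  stopifnot(inherits(x, "enm_raster"))
  is.finite(x$values) & x$values != x$spec$nodata
}

#' Bundle co-registered rasters into a stack
#'
#' A cell is valid in the stack iff it is valid in every layer.
#'
#' @param layers list of \code{enm_raster} objects sharing one geometry.
#' @return an object of class \code{"raster_stack"} with elements
#'   \code{layers} (named list), \code{spec} and \code{valid} (logical mask).
#' @export
raster_stack <- function(layers) {
  if (length(layers) < 1) abort("raster_stack needs at least one layer")
  stopifnot(all(vapply(layers, inherits, logical(1), "enm_raster")))
  spec <- layers[[1]]$spec
  for (i in seq_along(layers))
    if (!same_grid(spec, layers[[i]]$spec))
      abort("layer ", i, " (", layers[[i]]$name,
            ") is not co-registered with layer 1")
  names(layers) <- vapply(layers, `[[`, character(1), "name")
  if (anyDuplicated(names(layers))) abort("duplicate layer names in stack")
  valid <- Reduce(`&`, lapply(layers, valid_mask))
  structure(list(layers = layers, spec = spec, valid = valid),
            class = "raster_stack")
}

## ---- cell <-> coordinate conversions ------------------------------------

## Column-major single index of cell (row, col) in an n_rows x n_cols matrix.
cell_index <- function(row, col, spec) (col - 1L) * spec$n_rows + row

cell_row <- function(cell, spec) ((cell - 1L) %% spec$n_rows) + 1L
cell_col <- function(cell, spec) ((cell - 1L) %/% spec$n_rows) + 1L

#' Cell centers of grid cells
#'
#' @param cell column-major cell indices.
#' @param spec a \code{grid_spec}.
#' @return two-column matrix of (lon, lat) cell-center coordinates.
#' @export
cell_center <- function(cell, spec) {
  r <- cell_row(cell, spec); c <- cell_col(cell, spec)
  cbind(lon = spec$x_ll + (c - 0.5) * spec$cell_size,
        lat = spec$y_ll + (spec$n_rows - r + 0.5) * spec$cell_size)
}

#' Snap points to grid cells
#'
#' Uses the half-open convention: a point with \code{x} in
#' \code{[left, right)} of a column belongs to that column (likewise rows),
#' so snapping is deterministic on cell boundaries.
#'
#' @param lon,lat point coordinates in degrees.
#' @param spec a \code{grid_spec}.
#' @return integer vector of column-major cell indices; \code{NA} for points
#'   outside the grid extent.
#' @export
point_to_cell <- function(lon, lat, spec) {
  col <- floor((lon - spec$x_ll) / spec$cell_size) + 1
  row <- spec$n_rows - floor((lat - spec$y_ll) / spec$cell_size)
  bad <- col < 1 | col > spec$n_cols | row < 1 | row > spec$n_rows
  out <- cell_index(as.integer(row), as.integer(col), spec)
  out[bad] <- NA_integer_
  out
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols, cell %g deg, ll corner (%g, %g), nodata %g\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_ll, x$y_ll, x$nodata))
  invisible(x)
}

#' @export
print.enm_raster <- function(x, ...) {
  v <- x$values[valid_mask(x)]
  cat(sprintf("enm_raster '%s': %d x %d, %d valid cells, range [%g, %g]\n",
              x$name, x$spec$n_rows, x$spec$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layers (%s), %d x %d, %d jointly valid cells\n",
              length(x$layers), paste(names(x$layers), collapse = ", "),
              x$spec$n_rows, x$spec$n_cols, sum(x$valid)))
  invisible(x)
}
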