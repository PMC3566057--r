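## ESRI ASCII grid (.asc) reader/writer.  This is the de-facto exchange
## format for presence-background niche-modelling layers; the format is
## plain whitespace-separated text with a six-line header.  Readers reject
## malformed input rather than repairing it.

ASC_HEADER <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "nodata_value")

#' Read an ESRI ASCII grid
#'
#' Row 1 of the returned value matrix is the northernmost row, as in the
#' file.  Header keywords are matched case-insensitively; all six
#' (NCOLS, NROWS, XLLCORNER, YLLCORNER, CELLSIZE, NODATA_VALUE) are
#' required, in that order.
#'
#' @param path file path.
#' @param name variable label for the returned raster; defaults to the file
#'   name without extension.
#' @return an \code{\link{enm_raster}}.
#' @export
read_ascii_grid <- function(path, name = NULL) {
  if (!file.exists(path)) abort("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 7) abort(path, ": too short for an ASCII grid (line 1)")
  hdr <- list()
  for (i in seq_len(6)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 2)
      abort(path, ": malformed header at line ", i, ": '", lines[i], "'")
    key <- tolower(tok[1])
    if (key != ASC_HEADER[i])
      abort(path, ": expected header token '", toupper(ASC_HEADER[i]),
            "' at line ", i, ", found '", tok[1], "'")
    val <- suppressWarnings(as.numeric(tok[2]))
    if (is.na(val)) abort(path, ": non-numeric header value at line ", i)
    hdr[[key]] <- val
  }
  spec <- grid_spec(n_rows = hdr$nrows, n_cols = hdr$ncols,
                    cell_size = hdr$cellsize,
                    x_ll = hdr$xllcorner, y_ll = hdr$yllcorner,
                    nodata = hdr$nodata_value)
  body <- lines[-(1:6)]
  toks <- scan(text = paste(body, collapse = "\n"), what = double(),
               quiet = TRUE)
  n_exp <- spec$n_rows * spec$n_cols
  if (length(toks) != n_exp)
    abort(path, ": expected ", n_exp, " values after line 6, found ",
          length(toks))
  values <- matrix(toks, nrow = spec$n_rows, ncol = spec$n_cols, byrow = TRUE)
  enm_raster(values, spec,
             name = name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write an ESRI ASCII grid
#'
#' Values are written with 15 significant digits, so integers round-trip
#' exactly and reals round-trip to well under 1e-9 relative error.
#'
#' @param raster an \code{\link{enm_raster}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(raster, path) {
  stopifnot(inherits(raster, "enm_raster"))
  spec <- raster$spec
  if (spec$n_rows < 1 || spec$n_cols < 1) abort("empty-extent raster")
  num <- function(x) sprintf("%.15g", x)
  hdr <- c(paste("NCOLS", spec$n_cols),
           paste("NROWS", spec$n_rows),
           paste("XLLCORNER", num(spec$x_ll)),
           paste("YLLCORNER", num(spec$y_ll)),
           paste("CELLSIZE", num(spec$cell_size)),
           paste("NODATA_VALUE", num(spec$nodata)))
  rows <- apply(raster$values, 1, function(r) paste(num(r), collapse = " "))
  con <- file(path, "wb")  # binary connection: stable LF endings
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n")
  invisible(path)
}

#' Read a directory of ASCII grids into a stack
#'
#' @param paths character vector of .asc files (or a directory, in which
#'   case all \code{*.asc} files in it are read in sorted order).
#' @return a \code{\link{raster_stack}}.
#' @export
read_layer_stack <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.asc$", full.names = TRUE))
  if (length(paths) == 0) abort("no .asc layers found")
  raster_stack(lapply(paths, read_ascii_grid))
}
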