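## Niche overlap between RAW suitability surfaces: Schoener's D and the
## Hellinger-derived I of Warren et al.'s framework.  Both operate on two
## unit-mass probability distributions over the same cells and range from
## 0 (no overlap) to 1 (identical distributions).

## Coerce a pair of surfaces (or bare numeric weight vectors) to two
## probability vectors on their common valid support, renormalized to unit
## mass over that support.
overlap_pair <- function(pX, pY) {
  if (inherits(pX, "suitability") || inherits(pY, "suitability")) {
    stopifnot(inherits(pX, "suitability"), inherits(pY, "suitability"))
    if (!same_grid(pX$spec, pY$spec))
      abort("surfaces are not co-registered")
    common <- pX$valid & pY$valid
    if (!any(common)) abort("surfaces share no valid cells")
    x <- pX$values[common]; y <- pY$values[common]
  } else {
    x <- as.numeric(pX); y <- as.numeric(pY)
    if (length(x) != length(y)) abort("weight vectors differ in length")
    if (any(x < 0) || any(y < 0)) abort("weights must be nonnegative")
  }
  sx <- sum(x); sy <- sum(y)
  if (sx <= 0 || sy <= 0) abort("zero total mass on the common support")
  list(x = x / sx, y = y / sy)
}

#' Schoener's D niche overlap
#'
#' \code{D = 1 - 0.5 * sum_i |p_i - q_i|} between two unit-mass suitability
#' distributions.  1 means complete niche overlap, 0 none.
#'
#' @param pX,pY \code{\link{suitability_surface}} objects (co-registered)
#'   or bare nonnegative weight vectors of equal length.
#' @return a number in [0, 1]; symmetric in its arguments.
#' @export
schoener_D <- function(pX, pY) {
  pq <- overlap_pair(pX, pY)
  min(max(1 - 0.5 * sum(abs(pq$x - pq$y)), 0), 1)
}

#' Hellinger-based I niche overlap
#'
#' \code{I = 1 - 0.5 * H^2} where \code{H} is the Hellinger distance:
#' \code{I = 1 - 0.5 * sum_i (sqrt(p_i) - sqrt(q_i))^2}.
#'
#' @inheritParams schoener_D
#' @return a number in [0, 1]; symmetric in its arguments.
#' @export
hellinger_I <- function(pX, pY) {
  pq <- overlap_pair(pX, pY)
  min(max(1 - 0.5 * sum((sqrt(pq$x) - sqrt(pq$y))^2), 0), 1)
}

#' Pairwise niche overlap matrix
#'
#' D above the diagonal, I below, 1 on the diagonal.
#'
#' @param surfaces named list of co-registered
#'   \code{\link{suitability_surface}} objects (>= 2, unique names).
#' @param clades optional named clade vector (per species) carried as an
#'   annotation.
#' @return an object of class \code{"overlap_matrix"}: the square matrix
#'   \code{values} plus \code{species} and \code{clades}.
#' @export
overlap_matrix <- function(surfaces, clades = NULL) {
  if (length(surfaces) < 2) abort("need at least 2 surfaces")
  species <- names(surfaces) %||%
    vapply(surfaces, `[[`, character(1), "name")
  if (anyDuplicated(species)) abort("duplicate species labels")
  n <- length(surfaces)
  M <- diag(1, n)
  dimnames(M) <- list(species, species)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- schoener_D(surfaces[[i]], surfaces[[j]])   # D above diagonal
    M[j, i] <- hellinger_I(surfaces[[i]], surfaces[[j]])  # I below diagonal
  }
  structure(list(values = M, species = species,
                 clades = if (!is.null(clades)) clades[species]),
            class = "overlap_matrix")
}

## Band labels mirroring the figure legend: light shading for overlap in
## [0.11, 0.50], dark above 0.50.
overlap_band <- function(v) {
  ifelse(v > 0.5, "dark", ifelse(v >= 0.11, "light", "none"))
}

#' Write an overlap matrix as annotated long-format CSV
#'
#' Values are reported to 2 decimals (full precision is kept in the
#' \code{overlap_matrix} object); a \code{band} style column flags values
#' in [0.11, 0.50] ("light") and above 0.50 ("dark").
#'
#' @param om an \code{\link{overlap_matrix}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_overlap_csv <- function(om, path) {
  stopifnot(inherits(om, "overlap_matrix"))
  n <- length(om$species)
  rows <- do.call(rbind, lapply(seq_len(n), function(i)
    do.call(rbind, lapply(seq_len(n), function(j) {
      if (i == j) return(NULL)
      data.frame(species_a = om$species[i], species_b = om$species[j],
                 statistic = if (i < j) "D" else "I",
                 value = round(om$values[i, j], 2),
                 band = overlap_band(om$values[i, j]),
                 clade_a = if (!is.null(om$clades))
                   om$clades[om$species[i]] else NA,
                 clade_b = if (!is.null(om$clades))
                   om$clades[om$species[j]] else NA)
    }))))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("overlap_matrix (D above diagonal, I below):\n")
  print(round(x$values, 2))
  invisible(x)
}
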