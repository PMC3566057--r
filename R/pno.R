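## Predicted niche occupancy (PNO) profiles: a species' RAW suitability
## distribution integrated over the values of one climate variable,
## yielding a unit-mass histogram of suitability across that variable's
## range.  Bin edges are computed from the variable's global (study-wide)
## range so that profiles of different species are directly comparable on
## one axis.

#' Compute a predicted niche occupancy profile
#'
#' The variable's valid range is divided into \code{n_bins} equally spaced
#' bins; the mass of bin b is the summed suitability of the cells whose
#' variable value falls in [edge_b, edge_{b+1}) (last bin closed above),
#' renormalized to unit mass.
#'
#' @param surface a \code{\link{suitability_surface}}.
#' @param variable_raster the co-registered climate layer
#'   (\code{\link{enm_raster}}).
#' @param n_bins number of bins (default 50).
#' @param range optional c(lo, hi) bin range; by default the global
#'   min/max of the variable over its valid cells, which is shared by all
#'   species on the same layer.
#' @return an object of class \code{"pno_profile"}: \code{variable},
#'   \code{species}, \code{edges} (length n_bins + 1), \code{mids},
#'   \code{mass} (sums to 1).
#' @export
compute_pno <- function(surface, variable_raster, n_bins = 50,
                        range = NULL) {
  stopifnot(inherits(surface, "suitability"),
            inherits(variable_raster, "enm_raster"))
  if (!same_grid(surface$spec, variable_raster$spec))
    abort("surface and variable raster are not co-registered")
  if (n_bins < 2) abort("n_bins must be >= 2")
  vmask <- valid_mask(variable_raster)
  if (is.null(range)) {
    vv <- variable_raster$values[vmask]
    range <- c(min(vv), max(vv))
  }
  if (diff(range) <= 0)
    abort("variable '", variable_raster$name,
          "' has zero range; cannot bin")
  edges <- seq(range[1], range[2], length.out = n_bins + 1)
  cells <- which(surface$valid & vmask)
  x <- variable_raster$values[cells]
  p <- surface$values[cells]
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= n_bins
  mass <- numeric(n_bins)
  acc <- tapply(p[keep], bin[keep], sum)
  mass[as.integer(names(acc))] <- acc
  tot <- sum(mass)
  if (tot <= 0) abort("no suitability mass falls inside the bin range")
  mass <- mass / tot
  structure(list(variable = variable_raster$name, species = surface$name,
                 edges = edges, mids = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                 mass = mass, n_bins = as.integer(n_bins)),
            class = "pno_profile")
}

#' Suitability-weighted mean of a PNO profile
#'
#' Bin midpoints weighted by bin mass: the species' mean climatic
#' tolerance for the variable.
#'
#' @param profile a \code{\link{pno_profile}}.
#' @return value in variable units.
#' @export
pno_weighted_mean <- function(profile) {
  stopifnot(inherits(profile, "pno_profile"))
  sum(profile$mids * profile$mass)
}

#' Draw values from a PNO profile
#'
#' Bin midpoints are drawn with probability equal to bin mass, with
#' replacement.  With \code{jitter = TRUE} draws are instead uniform
#' within the drawn bin.
#'
#' @param profile a \code{\link{pno_profile}}.
#' @param n_draws number of draws (default 100).
#' @param seed RNG seed.
#' @param jitter uniform within-bin jitter (default FALSE: midpoints).
#' @return numeric vector of \code{n_draws} values.
#' @export
sample_pno <- function(profile, n_draws = 100, seed = 1, jitter = FALSE) {
  stopifnot(inherits(profile, "pno_profile"))
  if (n_draws < 1) abort("n_draws must be >= 1")
  with_seed(seed, {
    b <- sample.int(profile$n_bins, n_draws, replace = TRUE,
                    prob = profile$mass)
    if (jitter) {
      w <- diff(profile$edges)[b]
      profile$edges[b] + stats::runif(n_draws) * w
    } else {
      profile$mids[b]
    }
  })
}

#' Write PNO profiles to long-format CSV
#'
#' @param profiles list of \code{\link{pno_profile}} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_pno_csv <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(variable = p$variable, species = p$species,
               bin_mid = p$mids, mass = p$mass)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pno_profile <- function(x, ...) {
  cat(sprintf("pno_profile: %s / %s, %d bins on [%g, %g], mean %g\n",
              x$species, x$variable, x$n_bins, x$edges[1],
              x$edges[length(x$edges)], pno_weighted_mean(x)))
  invisible(x)
}
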