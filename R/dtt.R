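## Disparity-through-time analysis: the observed relative-disparity curve,
## a Brownian-motion null distribution of such curves on the same tree,
## and the MDI statistic (signed area between observed curve and null
## median), whole-tree and per clade.

#' Disparity of a set of taxa
#'
#' The default metric is the mean of the squared pairwise differences
#' between taxon values; \code{metric = "euclidean"} uses the mean
#' absolute (Euclidean, scalar trait) pairwise distance instead.  A single
#' taxon has zero disparity.
#'
#' @param values named numeric vector of tip values.
#' @param taxa optional subset of taxa (default: all of \code{values}).
#' @param metric \code{"squared"} (default) or \code{"euclidean"}.
#' @return nonnegative number.
#' @export
clade_disparity <- function(values, taxa = NULL,
                            metric = c("squared", "euclidean")) {
  metric <- match.arg(metric)
  if (!is.null(taxa)) {
    unknown <- setdiff(taxa, names(values))
    if (length(unknown))
      abort("unknown taxa: ", paste(unknown, collapse = ", "))
    values <- values[taxa]
  }
  k <- length(values)
  if (k < 1) abort("need at least one taxon")
  if (k == 1) return(0)
  if (metric == "squared") {
    ## sum over unordered pairs of (zi - zj)^2 = k*sum(z^2) - sum(z)^2
    (k * sum(values^2) - sum(values)^2) / (k * (k - 1) / 2)
  } else {
    mean(stats::dist(values))
  }
}

## Precompute the crossing-lineage structure of a tree: for each branching
## time t (internal node height; relative, root = 0), the set of lineages
## alive immediately BEFORE the split at t, each represented by the node at
## the bottom of its subtending edge.  Just before the root split there is
## a single lineage, the whole tree, so the curve starts at 1.
dtt_structure <- function(phy) {
  validate_phylogeny(phy)
  n <- ape::Ntip(phy)
  h <- node_heights(phy)
  H <- max(h[seq_len(n)])
  tol <- 1e-9 * H
  int_h <- h[(n + 1L):(n + phy$Nnode)]
  times <- sort(unique(int_h))
  crossing <- lapply(times, function(t)
    phy$edge[h[phy$edge[, 1]] < t - tol & h[phy$edge[, 2]] >= t - tol, 2])
  crossing[[1]] <- n + 1L   # root time: the single whole-tree lineage
  list(n = n, heights = h, height = H, times = times / H,
       crossing = crossing)
}

## Disparity of the tip set under every node, computed by postorder
## accumulation of (count, sum, sum of squares); metric "euclidean" falls
## back to explicit pair enumeration per node.
node_disparities <- function(phy, x, metric = "squared") {
  n <- ape::Ntip(phy)
  nn <- n + phy$Nnode
  if (metric == "squared") {
    cnt <- c(rep(1, n), rep(0, phy$Nnode))
    s1 <- c(x, rep(0, phy$Nnode))
    s2 <- c(x^2, rep(0, phy$Nnode))
    po <- ape::reorder.phylo(phy, "postorder")
    for (e in seq_len(nrow(po$edge))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      cnt[p] <- cnt[p] + cnt[ch]
      s1[p] <- s1[p] + s1[ch]
      s2[p] <- s2[p] + s2[ch]
    }
    d <- numeric(nn)
    many <- cnt > 1
    d[many] <- (cnt[many] * s2[many] - s1[many]^2) /
      (cnt[many] * (cnt[many] - 1) / 2)
    pmax(d, 0)
  } else {
    tips_under <- lapply(seq_len(nn), function(k)
      if (k <= n) k else
        which(phy$tip.label %in% ape::extract.clade(phy, k)$tip.label))
    names(x) <- phy$tip.label
    vapply(tips_under, function(tp)
      clade_disparity(x[tp], metric = "euclidean"), numeric(1))
  }
}

#' Observed relative disparity-through-time curve
#'
#' At each branching time (internal-node height; relative time t, root =
#' 0, tips = 1) the curve value is the mean, over every lineage alive
#' immediately before the split at t, of the disparity of the lineage's
#' tip descendants divided by the disparity of the whole tree.  Lineages
#' subtending a single tip contribute zero disparity.  Just before the
#' root split the single lineage is the whole tree, so the curve starts at
#' 1; a final point (1, 0) is appended for the present, where every
#' lineage holds one tip.
#'
#' @param phy rooted ultrametric ape \code{phylo} tree.
#' @param tip_values named numeric vector of tip values (non-constant).
#' @param metric disparity metric, see \code{\link{clade_disparity}}.
#' @return an object of class \code{"dtt_curve"}: \code{times} (strictly
#'   increasing relative times, ending at 1), \code{disparity} (starting
#'   at 1, ending at 0) and \code{total_disparity}.
#' @export
relative_disparity_curve <- function(phy, tip_values,
                                     metric = c("squared", "euclidean")) {
  metric <- match.arg(metric)
  st <- dtt_structure(phy)
  curve_from_structure(phy, st, tip_values, metric)
}

## Core curve evaluation against a precomputed dtt_structure (reused by
## the null simulation, where the tree is fixed and only traits change).
curve_from_structure <- function(phy, st, tip_values, metric = "squared") {
  if (is.null(names(tip_values)))
    abort("tip_values must be named by tip label")
  if (!setequal(names(tip_values), phy$tip.label))
    abort("tip_values names do not match the tree's tip labels")
  x <- as.numeric(tip_values[phy$tip.label])
  d <- node_disparities(phy, x, metric)
  total <- d[ape::Ntip(phy) + 1L]
  if (total <= 0) abort("degenerate trait: all tip values are equal")
  vals <- vapply(st$crossing, function(nodes) mean(d[nodes]) / total,
                 numeric(1))
  structure(list(times = c(st$times, 1), disparity = c(vals, 0),
                 total_disparity = total, metric = metric),
            class = "dtt_curve")
}

#' Brownian-motion null distribution of DTT curves
#'
#' The BM rate is estimated from the observed tip values by
#' \code{\link{bm_ancestral_ml}}; \code{n_sim} neutral tip datasets are
#' then simulated on the same tree (the topology is fixed, only traits are
#' simulated) and each is turned into a DTT curve evaluated at the
#' observed node times.
#'
#' @param phy rooted ultrametric ape \code{phylo} tree.
#' @param tip_values observed named tip values.
#' @param n_sim number of simulations (default 1000).
#' @param seed RNG seed.
#' @param metric disparity metric.
#' @return an object of class \code{"dtt_null"}: \code{times},
#'   \code{median} (pointwise), \code{q05}, \code{q95}, \code{curves}
#'   (n_sim x n_times matrix), \code{sigma2}.
#' @export
simulate_bm_null <- function(phy, tip_values, n_sim = 1000, seed = 1,
                             metric = c("squared", "euclidean")) {
  metric <- match.arg(metric)
  if (n_sim < 1) abort("n_sim must be >= 1")
  st <- dtt_structure(phy)
  obs <- curve_from_structure(phy, st, tip_values, metric)  # validates data
  fit <- bm_ancestral_ml(phy, tip_values)
  n <- ape::Ntip(phy)
  R <- chol(ape::vcv(phy))   # upper-triangular, t(R) %*% R = V
  curves <- with_seed(seed, {
    t(vapply(seq_len(n_sim), function(s) {
      z <- fit$root + sqrt(fit$sigma2) *
        as.vector(crossprod(R, stats::rnorm(n)))
      names(z) <- rownames(R)
      curve_from_structure(phy, st, z, metric)$disparity
    }, numeric(length(obs$times))))
  })
  structure(list(times = obs$times,
                 median = apply(curves, 2, stats::median),
                 q05 = apply(curves, 2, stats::quantile, 0.05),
                 q95 = apply(curves, 2, stats::quantile, 0.95),
                 curves = curves, sigma2 = fit$sigma2, n_sim = n_sim),
            class = "dtt_null")
}

#' Morphological disparity index (MDI)
#'
#' Signed area, by the trapezoid rule over relative time, between the
#' observed DTT curve and the pointwise median of the BM null curves.
#' Positive MDI: observed disparity lies above the null, i.e. disparity is
#' distributed within subclades (niche evolution inside clades); negative
#' MDI: disparity lies among subclades (niche conservatism within them).
#'
#' @param observed a \code{\link{relative_disparity_curve}} result.
#' @param null a \code{\link{simulate_bm_null}} result, or a bare numeric
#'   median curve on the same time grid.
#' @return the signed MDI value.
#' @export
mdi <- function(observed, null) {
  stopifnot(inherits(observed, "dtt_curve"))
  med <- if (inherits(null, "dtt_null")) {
    if (!isTRUE(all.equal(observed$times, null$times)))
      abort("observed and null curves are on different time grids")
    null$median
  } else {
    if (length(null) != length(observed$times))
      abort("null median curve length does not match the time grid")
    as.numeric(null)
  }
  dfun <- observed$disparity - med
  dt <- diff(observed$times)
  sum((dfun[-1] + dfun[-length(dfun)]) / 2 * dt)
}

#' Clade-wise DTT and MDI
#'
#' Extracts each clade's subtree (branch lengths preserved, re-rooted at
#' the clade MRCA; relative time rescaled to the subtree's own height) and
#' runs the full DTT + BM null + MDI analysis on it.  Clades with fewer
#' than \code{min_tips} tips are skipped with a warning.
#'
#' @param phy rooted ultrametric ape \code{phylo} tree.
#' @param clades named clade vector (see \code{\link{clade_map}}).
#' @param tip_values named numeric tip values.
#' @param n_sim null simulations per clade (default 1000).
#' @param seed RNG seed.
#' @param metric disparity metric.
#' @param min_tips minimum clade size for a meaningful curve (default 3).
#' @return data.frame: clade, n_tips, mdi (NA when skipped), n_sim.
#' @export
clade_dtt <- function(phy, clades, tip_values, n_sim = 1000, seed = 1,
                      metric = c("squared", "euclidean"), min_tips = 3) {
  metric <- match.arg(metric)
  clades <- clade_map(clades, phy)
  out <- lapply(unique(clades), function(cl) {
    members <- names(clades)[clades == cl]
    if (length(members) < min_tips) {
      warning("clade '", cl, "' has ", length(members),
              " tips (< ", min_tips, "); skipped", call. = FALSE)
      return(data.frame(clade = cl, n_tips = length(members),
                        mdi = NA_real_, n_sim = n_sim))
    }
    sub <- ape::extract.clade(phy, ape::getMRCA(phy, members))
    vals <- tip_values[sub$tip.label]
    obs <- relative_disparity_curve(sub, vals, metric)
    nul <- simulate_bm_null(sub, vals, n_sim,
                            seed = derive_seed(seed, paste0("clade:", cl)),
                            metric = metric)
    data.frame(clade = cl, n_tips = length(members), mdi = mdi(obs, nul),
               n_sim = n_sim)
  })
  do.call(rbind, out)
}

#' Full DTT stage: PNO tip values, whole-tree and per-clade MDI
#'
#' The tip value of each species for each variable is its
#' suitability-weighted PNO mean; for each variable the observed DTT
#' curve, BM null and MDI are computed on the whole tree and (when a clade
#' map is given) per clade.
#'
#' @param phy rooted ultrametric ape \code{phylo} tree.
#' @param profiles_by_var list (by variable) of named lists of
#'   \code{\link{pno_profile}} objects (by species).
#' @param clades optional named clade vector.
#' @param n_sim null simulations (default 1000).
#' @param seed RNG seed.
#' @param metric disparity metric.
#' @return list: \code{table} (data.frame variable, scope, mdi, n_sim,
#'   seed), \code{curves} (per variable: observed \code{dtt_curve} and
#'   \code{dtt_null}).
#' @export
dtt_pipeline <- function(phy, profiles_by_var, clades = NULL,
                         n_sim = 1000, seed = 1,
                         metric = c("squared", "euclidean")) {
  metric <- match.arg(metric)
  rows <- list(); curves <- list()
  for (v in names(profiles_by_var)) {
    profs <- profiles_by_var[[v]]
    tips <- vapply(profs, pno_weighted_mean, numeric(1))
    names(tips) <- names(profs)
    obs <- relative_disparity_curve(phy, tips, metric)
    nul <- simulate_bm_null(phy, tips, n_sim,
                            seed = derive_seed(seed, paste0("dtt:", v)),
                            metric = metric)
    rows[[length(rows) + 1L]] <-
      data.frame(variable = v, scope = "all", mdi = mdi(obs, nul),
                 n_sim = n_sim, seed = seed)
    if (!is.null(clades)) {
      cl <- clade_dtt(phy, clades, tips, n_sim,
                      seed = derive_seed(seed, paste0("cdtt:", v)),
                      metric = metric)
      rows[[length(rows) + 1L]] <-
        data.frame(variable = v, scope = cl$clade, mdi = cl$mdi,
                   n_sim = n_sim, seed = seed)
    }
    curves[[v]] <- list(observed = obs, null = nul)
  }
  list(table = do.call(rbind, rows), curves = curves)
}

#' Write a DTT curve and its null envelope to CSV
#'
#' @param observed a \code{dtt_curve}.
#' @param null a \code{dtt_null} on the same grid.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_dtt_csv <- function(observed, null, path) {
  df <- data.frame(t = observed$times, observed = observed$disparity,
                   null_median = null$median, null_q05 = null$q05,
                   null_q95 = null$q95)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
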