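# Fixtures are built in code: small grids, trees and datasets, plus the
# independent brute-force oracles used to cross-check the package's
# implementations.

tiny_spec <- function(n_rows = 4, n_cols = 5, cell_size = 1,
                      x_ll = 0, y_ll = 0, nodata = -9999) {
  grid_spec(n_rows, n_cols, cell_size, x_ll, y_ll, nodata)
}

random_raster <- function(spec, seed = 1, nodata_frac = 0) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(spec$n_rows * spec$n_cols), spec$n_rows, spec$n_cols)
    if (nodata_frac > 0) {
      k <- ceiling(nodata_frac * length(v))
      v[sample.int(length(v), k)] <- spec$nodata
    }
    v
  })
}

small_stack <- function(n_layers = 3, n_rows = 25, n_cols = 25, seed = 1) {
  cfg <- sim_config(n_taxa = 5, n_layers = n_layers, n_rows = n_rows,
                    n_cols = n_cols, seed = seed)
  simulate_climate_layers(cfg, seed = seed)
}

# uniform suitability surface over a stack's valid cells
uniform_surface <- function(stack, species = "u") {
  suitability_surface(matrix(1, stack$spec$n_rows, stack$spec$n_cols),
                      stack$spec, stack$valid, species = species)
}

# Explicit covariance-matrix GLS oracle for BM ancestral states: the root
# is the GLS generalized mean; an internal node u is estimated as
# root + c_u' V^{-1} (x - root), where c_u[i] is the height of the most
# recent common ancestor of u and tip i (shared path length from the root).
gls_ancestral_oracle <- function(phy, x) {
  n <- ape::Ntip(phy)
  h <- node_heights(phy)
  V <- ape::vcv(phy)
  Vi <- solve(V)
  xo <- x[rownames(V)]
  root_est <- as.numeric(sum(Vi %*% xo) / sum(Vi))
  path_to_root <- function(k) {
    out <- k
    while (k != n + 1) { k <- phy$edge[phy$edge[, 2] == k, 1]; out <- c(out, k) }
    out
  }
  tip_paths <- lapply(match(rownames(V), phy$tip.label), path_to_root)
  est <- vapply((n + 1):(n + phy$Nnode), function(u) {
    anc_u <- path_to_root(u)
    cu <- vapply(tip_paths, function(p) h[intersect(p, anc_u)[1]], numeric(1))
    root_est + as.numeric(t(cu) %*% Vi %*% (xo - root_est))
  }, numeric(1))
  list(root = root_est, ace = setNames(est, as.character((n + 1):(n + phy$Nnode))),
       sigma2 = as.numeric(t(xo - root_est) %*% Vi %*% (xo - root_est)) / n)
}

# Brute-force relative-disparity-through-time oracle: explicit crossing
# sets from the edge table, explicit pair enumeration for disparities,
# descendant tips via ape::extract.clade.
dtt_oracle <- function(phy, x) {
  n <- ape::Ntip(phy)
  h <- node_heights(phy)
  H <- max(h[seq_len(n)])
  disp <- function(vals) {
    if (length(vals) < 2) return(0)
    pr <- utils::combn(length(vals), 2)
    mean((vals[pr[1, ]] - vals[pr[2, ]])^2)
  }
  tips_under <- function(nd)
    if (nd <= n) phy$tip.label[nd] else ape::extract.clade(phy, nd)$tip.label
  total <- disp(x[phy$tip.label])
  times <- sort(unique(h[(n + 1):(n + phy$Nnode)]))
  vals <- vapply(seq_along(times), function(i) {
    if (i == 1) return(1)
    t <- times[i]
    cross <- phy$edge[h[phy$edge[, 1]] < t - 1e-9 * H &
                      h[phy$edge[, 2]] >= t - 1e-9 * H, 2]
    mean(vapply(cross, function(nd) disp(x[tips_under(nd)]), numeric(1))) / total
  }, numeric(1))
  list(times = c(times / H, 1), disparity = c(vals, 0))
}
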