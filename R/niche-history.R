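## Maximum-likelihood reconstruction of climatic tolerances at internal
## nodes under Brownian motion, repeated over draws from the species' PNO
## profiles, with 80% central-density summaries per node.
##
## The ancestral estimator is a two-pass Gaussian message-passing (pruning)
## algorithm on the tree.  Because all node states are jointly Gaussian
## under BM, the estimates equal the GLS/BLUP conditional expectations
## computed from the full phylogenetic covariance matrix, but in O(n) per
## trait; the test suite checks this equivalence against an explicit
## covariance-matrix oracle.

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Two passes over the tree: a pruning downpass combining tip values into
#' per-subtree Gaussian messages (yielding the GLS root estimate and the
#' ML rate), and an uppass conditioning every internal node on the data
#' outside its subtree.  The BM rate is the ML estimate (residual
#' quadratic form divided by n); the REML variant (divide by n - 1) is
#' also returned.
#'
#' @param phy rooted ultrametric binary ape \code{phylo} tree.
#' @param tip_values named numeric vector, one finite value per tip.
#' @return list: \code{ace} (named estimates for internal nodes, ape
#'   numbering \code{Ntip+1 ...}), \code{root} (the estimate at the root),
#'   \code{sigma2} (ML rate), \code{sigma2_reml}, \code{logLik}.
#' @export
bm_ancestral_ml <- function(phy, tip_values) {
  validate_phylogeny(phy)
  n <- ape::Ntip(phy)
  if (is.null(names(tip_values)))
    abort("tip_values must be named by tip label")
  if (!setequal(names(tip_values), phy$tip.label))
    abort("tip_values names do not match the tree's tip labels")
  x <- as.numeric(tip_values[phy$tip.label])
  if (any(!is.finite(x))) abort("non-finite tip values")
  nn <- n + phy$Nnode
  root <- n + 1L

  po <- ape::reorder.phylo(phy, "postorder")
  mu <- numeric(nn); v <- numeric(nn)
  mu[seq_len(n)] <- x                      # tips: exact observations
  sw <- numeric(nn); swm <- numeric(nn)    # precision sums at parents
  ## per-node children messages, for the contrast decomposition of sigma2
  ch_mu <- matrix(NA_real_, nn, 2); ch_d <- matrix(NA_real_, nn, 2)
  ch_n <- integer(nn)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (ch > n) {                          # finalize child's down message
      mu[ch] <- swm[ch] / sw[ch]
      v[ch] <- 1 / sw[ch]
    }
    d <- v[ch] + po$edge.length[e]
    if (d <= 0) abort("non-positive message variance (zero branch?)")
    sw[p] <- sw[p] + 1 / d
    swm[p] <- swm[p] + mu[ch] / d
    ch_n[p] <- ch_n[p] + 1L
    ch_mu[p, ch_n[p]] <- mu[ch]; ch_d[p, ch_n[p]] <- d
  }
  mu[root] <- swm[root] / sw[root]
  v[root] <- 1 / sw[root]

  ## ML sigma2 from the independent-contrast decomposition of the
  ## residual quadratic form (x - root)' V^{-1} (x - root)
  internal <- (n + 1L):nn
  Q <- sum((ch_mu[internal, 1] - ch_mu[internal, 2])^2 /
             (ch_d[internal, 1] + ch_d[internal, 2]))
  sigma2 <- Q / n
  sigma2_reml <- Q / (n - 1)
  ## profile log-likelihood at (root, sigma2); log|V| from the pruning
  ## message variances
  logdetV <- sum(log(ch_d[internal, 1]) + log(ch_d[internal, 2])) +
    log(v[root]) - sum(log(v[internal]))
  logLik <- -0.5 * (n * log(2 * pi * sigma2) + logdetV + Q / sigma2)

  ## uppass: message about each node from outside its subtree
  a <- numeric(nn); g <- rep(Inf, nn)
  cw <- ape::reorder.phylo(phy, "cladewise")   # parents precede children
  for (e in seq_len(nrow(cw$edge))) {
    p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
    len <- cw$edge.length[e]
    sw_ex <- sw[p] - 1 / (v[ch] + len)
    swm_ex <- swm[p] - mu[ch] / (v[ch] + len)
    if (is.finite(g[p])) {                 # p is not the root
      sw_ex <- sw_ex + 1 / g[p]
      swm_ex <- swm_ex + a[p] / g[p]
    }
    a[ch] <- swm_ex / sw_ex
    g[ch] <- 1 / sw_ex + len
  }

  est <- numeric(nn)
  est[root] <- mu[root]
  for (k in setdiff(internal, root)) {
    w1 <- 1 / v[k]; w2 <- 1 / g[k]
    est[k] <- (mu[k] * w1 + a[k] * w2) / (w1 + w2)
  }
  ace <- stats::setNames(est[internal], as.character(internal))
  list(ace = ace, root = est[root], sigma2 = sigma2,
       sigma2_reml = sigma2_reml, logLik = logLik)
}

#' Empirical central-density interval and its interior mean
#'
#' @param values numeric sample (>= 1 value).
#' @param mass central mass of the interval, in (0, 1); default 0.8.
#' @return named vector \code{c(low, high, mean_within)}: the
#'   [(1-mass)/2, 1-(1-mass)/2] empirical quantile interval and the mean
#'   of the values inside it.
#' @export
central_density <- function(values, mass = 0.8) {
  if (length(values) < 1) abort("empty sample")
  if (mass <= 0 || mass >= 1) abort("mass must be in (0, 1)")
  alpha <- (1 - mass) / 2
  q <- stats::quantile(values, c(alpha, 1 - alpha), names = FALSE)
  inside <- values >= q[1] & values <= q[2]
  c(low = q[1], high = q[2], mean_within = mean(values[inside]))
}

#' Reconstruct the history of one climatic variable over PNO draws
#'
#' For each of \code{n_draws} replicates, one value per species is drawn
#' from its PNO profile and ML ancestral states are computed under
#' Brownian motion; each internal node is then summarized by the mean of
#' its estimates across draws and the 80% central-density interval.
#'
#' @param phy rooted ultrametric ape \code{phylo} tree.
#' @param profiles named list of \code{\link{pno_profile}} objects, one
#'   per tip of \code{phy}, all for the same variable.
#' @param n_draws number of PNO draws (default 100).
#' @param seed RNG seed (per-species draw seeds are derived from it).
#' @param mass central-density mass for the node summaries (default 0.8).
#' @param jitter passed to \code{\link{sample_pno}}.
#' @return an object of class \code{"niche_history"}: \code{variable},
#'   \code{summary} (data.frame: node, mean, low, high, mean_within),
#'   \code{draws} (n_draws x n_internal matrix of node estimates),
#'   \code{tip_draws}, \code{sigma2} (mean ML rate across draws).
#' @export
reconstruct_history <- function(phy, profiles, n_draws = 100, seed = 1,
                                mass = 0.8, jitter = FALSE) {
  validate_phylogeny(phy)
  missing <- setdiff(phy$tip.label, names(profiles))
  if (length(missing))
    abort("missing PNO profiles for: ", paste(missing, collapse = ", "))
  profiles <- profiles[phy$tip.label]
  vars <- unique(vapply(profiles, `[[`, character(1), "variable"))
  if (length(vars) != 1)
    abort("profiles mix variables: ", paste(vars, collapse = ", "))
  n <- ape::Ntip(phy)
  tip_draws <- vapply(phy$tip.label, function(sp)
    sample_pno(profiles[[sp]], n_draws,
               seed = derive_seed(seed, paste0("pno:", sp)),
               jitter = jitter),
    numeric(n_draws))
  if (is.null(dim(tip_draws)))   # n_draws = 1 keeps its matrix shape
    tip_draws <- matrix(tip_draws, nrow = 1,
                        dimnames = list(NULL, phy$tip.label))
  internal <- as.character((n + 1L):(n + phy$Nnode))
  draws <- matrix(NA_real_, n_draws, length(internal),
                  dimnames = list(NULL, internal))
  sigma2 <- numeric(n_draws)
  for (d in seq_len(n_draws)) {
    fit <- bm_ancestral_ml(phy, tip_draws[d, ])
    draws[d, ] <- fit$ace[internal]
    sigma2[d] <- fit$sigma2
  }
  summ <- do.call(rbind, lapply(internal, function(nd) {
    cd <- central_density(draws[, nd], mass)
    data.frame(node = as.integer(nd), mean = mean(draws[, nd]),
               low = cd["low"], high = cd["high"],
               mean_within = cd["mean_within"], row.names = NULL)
  }))
  structure(list(variable = vars, summary = summ, draws = draws,
                 tip_draws = tip_draws, sigma2 = mean(sigma2),
                 n_draws = n_draws, mass = mass),
            class = "niche_history")
}

#' @export
print.niche_history <- function(x, ...) {
  cat(sprintf("niche_history: %s, %d draws, %d internal nodes (%.0f%% interval)\n",
              x$variable, x$n_draws, nrow(x$summary), 100 * x$mass))
  print(utils::head(x$summary))
  invisible(x)
}
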