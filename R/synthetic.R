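## Synthetic-data generator: every input the pipeline consumes (climate
## layers, dated tree, clade table, occurrences) can be produced here with
## known ground truth, so each downstream stage is testable end to end
## without external downloads.
##
## The generative model: a Yule tree; species niche optima evolving by
## Brownian motion along it; Gaussian (bell-shaped) response of suitability
## to each climate variable around the optimum; occurrence points sampled
## proportional to suitability, without replacement at cell level so points
## are spatially unique.

#' Plausible value ranges for the 19 bioclim-style variables
#'
#' Approximate tropical/subtropical Asian ranges of the standard 19
#' bioclimatic summaries (temperature in degrees C, temperature seasonality
#' as sd x 100, precipitation in mm, indices in percent).  Used to rescale
#' simulated climate fields to realistic units.
#'
#' @return data.frame with columns \code{name}, \code{lo}, \code{hi},
#'   \code{units}.
#' @export
bioclim_ranges <- function() {
  data.frame(
    name = sprintf("bio%02d", 1:19),
    lo = c(-5, 4, 25, 100, 10, -20, 9, 0, -10, 5, -15,
           200, 50, 0, 20, 120, 0, 50, 10),
    hi = c(28, 16, 95, 900, 38, 22, 33, 30, 28, 32, 25,
           4000, 900, 120, 140, 2200, 350, 2000, 700),
    units = c(rep("degC", 3), "sd x 100", rep("degC", 7),
              rep("mm", 3), "cv", rep("mm", 4)),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study conditions the pipeline was designed around:
#' 29 taxa in 4 clades, 19 bioclimatic layers at 0.0417 degree resolution,
#' and at least 10 spatially unique occurrence points per species.
#'
#' @param n_taxa number of species (tips).
#' @param n_clades number of labeled clades (oldest subtrees).
#' @param n_layers number of climate layers (at most 19).
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell size in degrees.
#' @param x_ll,y_ll lower-left corner (degrees).
#' @param autocorr_deg spatial autocorrelation length of the climate
#'   fields, in degrees (Gaussian smoothing kernel sd).
#' @param birth_rate Yule speciation rate (events/lineage/Myr before
#'   rescaling).
#' @param tree_height height of the chronogram in Myr.
#' @param tau_frac species climatic tolerance (Gaussian response sd) as a
#'   fraction of each variable's range.
#' @param sigma2_frac Brownian-motion tip standard deviation over the whole
#'   tree height, as a fraction of each variable's range; the per-variable
#'   BM rate is \code{(sigma2_frac * range)^2 / tree_height} per Myr.
#' @param n_points occurrence points per species (>= 10).
#' @param seed master seed.
#' @return an object of class \code{"sim_config"}.
#' @export
sim_config <- function(n_taxa = 29, n_clades = 4, n_layers = 19,
                       n_rows = 60, n_cols = 60, cell_size = 0.0417,
                       x_ll = 90, y_ll = 10, autocorr_deg = 0.3,
                       birth_rate = 1, tree_height = 10,
                       tau_frac = 0.15, sigma2_frac = 0.12,
                       n_points = 20, seed = 1) {
  cfg <- list(n_taxa = n_taxa, n_clades = n_clades, n_layers = n_layers,
              n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
              x_ll = x_ll, y_ll = y_ll, autocorr_deg = autocorr_deg,
              birth_rate = birth_rate, tree_height = tree_height,
              tau_frac = tau_frac, sigma2_frac = sigma2_frac,
              n_points = n_points, seed = seed)
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(num)) abort("all sim_config fields must be numeric")
  pos <- c("n_taxa", "n_clades", "n_layers", "n_rows", "n_cols",
           "cell_size", "autocorr_deg", "birth_rate", "tree_height",
           "tau_frac", "sigma2_frac", "n_points")
  bad <- pos[vapply(pos, function(f) cfg[[f]] <= 0, logical(1))]
  if (length(bad)) abort("sim_config fields must be positive: ",
                         paste(bad, collapse = ", "))
  if (n_points < 10)
    abort("n_points must be >= 10 (models require at least 10 spatially ",
          "unique points per species)")
  if (n_layers > 19) abort("at most 19 bioclim-style layers are defined")
  if (n_clades >= n_taxa) abort("n_clades must be < n_taxa")
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric Yule tree with a fixed number of tips
#'
#' Pure-birth process: the root splits at time 0 into two lineages; with
#' \code{k} lineages alive the waiting time to the next speciation is
#' exponential with rate \code{k * birth_rate} and a uniformly chosen
#' lineage splits.  After the \code{n_taxa}-th lineage appears, tips are
#' extended by one further exponential waiting time (the epoch at which the
#' next speciation would have occurred).
#'
#' @param n_taxa number of tips (>= 2).
#' @param birth_rate speciation rate per lineage.
#' @param seed RNG seed.
#' @param height if non-NULL, the tree is rescaled to this total height;
#'   \code{NULL} keeps the simulated natural time scale.
#' @param tip_prefix label prefix; tips are labeled
#'   \code{<prefix>01, <prefix>02, ...}.
#' @return a validated ape \code{phylo} object.
#' @export
simulate_yule_tree <- function(n_taxa, birth_rate = 1, seed = 1,
                               height = 1, tip_prefix = "sp") {
  if (n_taxa < 2) abort("n_taxa must be >= 2")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  with_seed(seed, {
    ## event times after the root split at t = 0
    t <- 0
    event_times <- numeric(0)
    if (n_taxa > 2)
      for (k in 2:(n_taxa - 1)) {
        t <- t + stats::rexp(1, k * birth_rate)
        event_times <- c(event_times, t)
      }
    T_end <- t + stats::rexp(1, n_taxa * birth_rate)

    ## node bookkeeping: internal nodes in creation order (1 = root)
    n_int <- n_taxa - 1
    int_parent <- rep(NA_integer_, n_int)   # parent internal node
    int_time <- numeric(n_int)
    int_time[1] <- 0
    slots <- c(1L, 1L)                       # open branches: parent node ids
    next_int <- 2L
    for (te in event_times) {
      i <- sample.int(length(slots), 1)
      int_parent[next_int] <- slots[i]
      int_time[next_int] <- te
      slots <- c(slots[-i], next_int, next_int)
      next_int <- next_int + 1L
    }
    ## remaining open branches become tips at T_end
    tip_parent <- slots
  })

  ## assemble a newick string at full precision and let ape parse it, so
  ## node numbering follows the standard cladewise convention
  scale <- if (is.null(height)) 1 else height / T_end
  tip_lab <- sprintf("%s%02d", tip_prefix, seq_len(n_taxa))
  int_kids <- lapply(seq_len(n_int), function(i) which(int_parent == i))
  tip_kids <- lapply(seq_len(n_int), function(i) which(tip_parent == i))
  nwk <- function(i) {
    parts <- c(
      vapply(int_kids[[i]], function(k)
        sprintf("%s:%.17g", nwk(k), (int_time[k] - int_time[i]) * scale),
        character(1)),
      vapply(tip_kids[[i]], function(k)
        sprintf("%s:%.17g", tip_lab[k], (T_end - int_time[i]) * scale),
        character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  phy <- ape::read.tree(text = paste0(nwk(1L), ";"))
  validate_phylogeny(phy)
  phy
}

## Gaussian random field on a torus: white noise smoothed by an isotropic
## Gaussian kernel (sd = len_cells) via FFT convolution, then standardized
## to mean 0, sd 1.
gaussian_field <- function(n_rows, n_cols, len_cells) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (len_cells > 0) {
    dr <- 0:(n_rows - 1); dr <- pmin(dr, n_rows - dr)
    dc <- 0:(n_cols - 1); dc <- pmin(dc, n_cols - dc)
    k <- exp(-outer(dr^2, dc^2, "+") / (2 * len_cells^2))
    k <- k / sum(k)
    noise <- Re(stats::fft(stats::fft(noise) * stats::fft(k),
                           inverse = TRUE)) / (n_rows * n_cols)
  }
  (noise - mean(noise)) / stats::sd(noise)
}

#' Simulate a stack of spatially autocorrelated climate layers
#'
#' Each layer is an independent Gaussian random field with the configured
#' autocorrelation length, affinely rescaled (min-max) to the plausible
#' range of the corresponding bioclim-style variable
#' (\code{\link{bioclim_ranges}}).
#'
#' @param config a \code{\link{sim_config}}.
#' @param seed RNG seed (defaults to the config's master seed).
#' @return a \code{\link{raster_stack}} with \code{config$n_layers} layers
#'   named \code{bio01, bio02, ...}.
#' @export
simulate_climate_layers <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  spec <- grid_spec(config$n_rows, config$n_cols, config$cell_size,
                    config$x_ll, config$y_ll)
  rng <- bioclim_ranges()[seq_len(config$n_layers), ]
  len_cells <- config$autocorr_deg / config$cell_size
  layers <- with_seed(seed, lapply(seq_len(config$n_layers), function(i) {
    f <- gaussian_field(config$n_rows, config$n_cols, len_cells)
    f01 <- (f - min(f)) / (max(f) - min(f))
    enm_raster(rng$lo[i] + f01 * (rng$hi[i] - rng$lo[i]), spec,
               name = rng$name[i])
  }))
  raster_stack(layers)
}

#' Evolve species niche optima by Brownian motion along a tree
#'
#' Each variable evolves independently: the state of a child node is its
#' parent's state plus a Normal(0, sigma2 * branch length) increment.
#'
#' @param phy ultrametric ape \code{phylo} tree.
#' @param n_vars number of variables.
#' @param sigma2 BM rate(s), variable units squared per unit branch length;
#'   scalar or length \code{n_vars}.
#' @param root_state root state(s); scalar or length \code{n_vars}.
#' @param seed RNG seed.
#' @return numeric matrix (tips x variables), rownames = tip labels.
#' @export
evolve_niche_optima <- function(phy, n_vars, sigma2, root_state = 0,
                                seed = 1) {
  validate_phylogeny(phy)
  if (any(sigma2 <= 0)) abort("sigma2 must be > 0")
  sigma2 <- rep_len(sigma2, n_vars)
  root_state <- rep_len(root_state, n_vars)
  n_tip <- ape::Ntip(phy)
  root <- n_tip + 1L
  states <- matrix(NA_real_, n_tip + phy$Nnode, n_vars)
  states[root, ] <- root_state
  phy_cw <- ape::reorder.phylo(phy, "cladewise")  # parents precede children
  with_seed(seed, {
    for (e in seq_len(nrow(phy_cw$edge))) {
      p <- phy_cw$edge[e, 1]; ch <- phy_cw$edge[e, 2]
      states[ch, ] <- states[p, ] +
        stats::rnorm(n_vars, 0, sqrt(sigma2 * phy_cw$edge.length[e]))
    }
  })
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  colnames(out) <- sprintf("bio%02d", seq_len(n_vars))
  out
}

#' Species niche specification (Gaussian response)
#'
#' @param mu named numeric vector of optima, one per climate variable.
#' @param tau named numeric vector of tolerance widths (sd of the Gaussian
#'   response), same names as \code{mu}; all > 0.
#' @return an object of class \code{"niche_spec"}.
#' @export
niche_spec <- function(mu, tau) {
  if (is.null(names(mu))) abort("mu must be named by variable")
  tau <- rep_len(tau, length(mu))
  if (any(tau <= 0)) abort("tau must be > 0")
  names(tau) <- names(mu)
  structure(list(mu = mu, tau = tau), class = "niche_spec")
}

#' True suitability surface implied by a Gaussian niche
#'
#' Cell weight is proportional to
#' \code{prod_v exp(-(x_v - mu_v)^2 / (2 tau_v^2))} over jointly valid
#' cells, normalized to unit mass.
#'
#' @param niche a \code{\link{niche_spec}} whose variables are layers of
#'   \code{stack}.
#' @param stack a \code{\link{raster_stack}}.
#' @param species species label attached to the surface.
#' @return a \code{\link{suitability_surface}}.
#' @export
suitability_from_niche <- function(niche, stack, species = "truth") {
  stopifnot(inherits(niche, "niche_spec"), inherits(stack, "raster_stack"))
  vars <- names(niche$mu)
  missing <- setdiff(vars, names(stack$layers))
  if (length(missing)) abort("niche variables not in stack: ",
                             paste(missing, collapse = ", "))
  if (!any(stack$valid)) abort("all cells of the stack are invalid")
  logw <- matrix(0, stack$spec$n_rows, stack$spec$n_cols)
  for (v in vars) {
    x <- stack$layers[[v]]$values
    logw <- logw - (x - niche$mu[v])^2 / (2 * niche$tau[v]^2)
  }
  logw[!stack$valid] <- -Inf
  suitability_surface(exp(logw - max(logw[stack$valid])), stack$spec,
                      stack$valid, species = species)
}

#' Sample spatially unique occurrence points from a suitability surface
#'
#' Cells are drawn with probability equal to their suitability weight,
#' without replacement across cells, and each point is placed at its cell
#' center.
#'
#' @param surface a \code{\link{suitability_surface}}.
#' @param n_points number of points (>= 1).
#' @param seed RNG seed.
#' @param species label for the returned set (defaults to the surface's).
#' @return an \code{\link{occurrence_set}}.
#' @export
sample_occurrences <- function(surface, n_points, seed = 1,
                               species = surface$name) {
  stopifnot(inherits(surface, "suitability"))
  if (n_points < 1) abort("n_points must be >= 1")
  w <- as.vector(surface$values)
  pos <- which(w > 0)
  if (n_points > length(pos))
    abort("n_points = ", n_points, " exceeds the ", length(pos),
          " cells with positive suitability")
  cells <- with_seed(seed,
    pos[sample.int(length(pos), n_points, prob = w[pos])])
  occurrence_set(species, sort(cells), surface$spec)
}

#' Partition tips into the oldest subtrees as labeled clades
#'
#' Starts from the root's two daughters and repeatedly splits the group
#' whose defining internal node is oldest (smallest height) until
#' \code{n_clades} groups remain, guaranteeing monophyly of every clade.
#'
#' @param phy ultrametric ape \code{phylo} tree.
#' @param n_clades number of clades.
#' @param labels clade labels (recycled with generic names if too few).
#' @return a validated named clade vector (see \code{\link{clade_map}}).
#' @export
assign_clades <- function(phy, n_clades,
                          labels = c("ruficollis", "schisticeps",
                                     "ferruginosus", "hypoleucos")) {
  validate_phylogeny(phy)
  n_tip <- ape::Ntip(phy)
  h <- node_heights(phy)
  children <- function(node) phy$edge[phy$edge[, 1] == node, 2]
  groups <- as.list(children(n_tip + 1L))
  while (length(groups) < n_clades) {
    internal <- vapply(groups, function(g) g > n_tip, logical(1))
    if (!any(internal)) abort("tree too small to cut into ", n_clades,
                              " clades")
    cand <- which(internal)
    split_at <- cand[which.min(h[unlist(groups[cand])])]
    groups <- c(groups[-split_at], as.list(children(groups[[split_at]])))
  }
  if (length(labels) < n_clades)
    labels <- c(labels, sprintf("clade%02d", seq_len(n_clades)))
  map <- character(n_tip)
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    tips <- if (g <= n_tip) g else
      ape::extract.clade(phy, g)$tip.label
    if (is.numeric(tips)) tips <- phy$tip.label[tips]
    map[match(tips, phy$tip.label)] <- labels[i]
  }
  clade_map(stats::setNames(map, phy$tip.label), phy)
}

#' Generate a complete synthetic dataset on disk
#'
#' Orchestrates the generator: climate layers (.asc), a dated Yule tree
#' (newick), a clade table (CSV), per-species occurrences (CSV) and a
#' ground-truth JSON (niche optima, tolerances, BM rates and root states)
#' sufficient to score parameter recovery downstream.  Reruns with the same
#' config are byte-identical.
#'
#' @param config a \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory objects (\code{tree},
#'   \code{stack}, \code{occurrences}, \code{clades}, \code{truth}) and the
#'   file \code{paths}.
#' @export
make_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stack <- simulate_climate_layers(config,
                                   seed = derive_seed(config$seed, "climate"))
  phy <- simulate_yule_tree(config$n_taxa, config$birth_rate,
                            seed = derive_seed(config$seed, "tree"),
                            height = config$tree_height)
  clades <- assign_clades(phy, config$n_clades)

  rng <- bioclim_ranges()[seq_len(config$n_layers), ]
  span <- rng$hi - rng$lo
  sigma2 <- (config$sigma2_frac * span)^2 / config$tree_height
  root_state <- rng$lo + span / 2
  tau <- config$tau_frac * span
  optima <- evolve_niche_optima(phy, config$n_layers, sigma2, root_state,
                                seed = derive_seed(config$seed, "niche"))

  occurrences <- lapply(phy$tip.label, function(sp) {
    ns <- niche_spec(stats::setNames(optima[sp, ], rng$name), tau)
    surf <- suitability_from_niche(ns, stack, species = sp)
    sample_occurrences(surf, config$n_points,
                       seed = derive_seed(config$seed, paste0("occ:", sp)),
                       species = sp)
  })
  names(occurrences) <- phy$tip.label

  paths <- list(
    layers = file.path(out_dir, paste0(rng$name, ".asc")),
    tree = file.path(out_dir, "tree.nwk"),
    occurrences = file.path(out_dir, "occurrences.csv"),
    clades = file.path(out_dir, "clades.csv"),
    truth = file.path(out_dir, "truth.json"),
    config = file.path(out_dir, "config.yaml")
  )
  for (i in seq_len(config$n_layers))
    write_ascii_grid(stack$layers[[i]], paths$layers[i])
  write_newick(phy, paths$tree)
  write_occurrences(occurrences, paths$occurrences)
  utils::write.csv(data.frame(taxon = names(clades),
                              clade = unname(clades)),
                   paths$clades, row.names = FALSE, quote = FALSE)
  truth <- list(seed = config$seed,
                variables = rng$name,
                sigma2 = stats::setNames(as.list(sigma2), rng$name),
                root_state = stats::setNames(as.list(root_state), rng$name),
                tau = stats::setNames(as.list(tau), rng$name),
                tree_height = config$tree_height,
                optima = apply(optima, 1, function(r)
                  stats::setNames(as.list(r), rng$name), simplify = FALSE))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  yaml::write_yaml(unclass(config), paths$config)

  invisible(list(dir = out_dir, tree = phy, stack = stack,
                 occurrences = occurrences, clades = clades,
                 truth = truth, paths = paths))
}
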