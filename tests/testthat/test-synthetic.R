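test_that("Yule simulator produces valid reproducible trees", {
  phy2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(phy2), 2)
  expect_equal(phy2$edge.length[1], phy2$edge.length[2])  # single cherry

  a <- simulate_yule_tree(12, seed = 9)
  b <- simulate_yule_tree(12, seed = 9)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_false(identical(ape::write.tree(a),
                         ape::write.tree(simulate_yule_tree(12, seed = 10))))
  expect_silent(validate_phylogeny(a))
  expect_equal(tree_height(a), 1, tolerance = 1e-12)
  expect_error(simulate_yule_tree(1), "n_taxa")
})

test_that("mean lineage count grows like the Yule expectation 2*exp(lambda*t)", {
  # starting from the root split (2 lineages), E[N(t)] = 2 e^{lambda t};
  # lineages at t = 2 + number of internal nodes (after the root) below t
  lambda <- 1; t_at <- 1
  counts <- vapply(1:1000, function(s) {
    phy <- simulate_yule_tree(60, birth_rate = lambda, seed = 20000 + s,
                              height = NULL)
    n <- ape::Ntip(phy)
    h <- node_heights(phy)[(n + 2):(n + phy$Nnode)]
    2 + sum(h <= t_at)
  }, numeric(1))
  expected <- 2 * exp(lambda * t_at)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * se + 0.01)
})

test_that("climate fields are autocorrelated, seed-stable, and span their range", {
  cfg <- sim_config(n_taxa = 5, n_layers = 2, n_rows = 40, n_cols = 40,
                    autocorr_deg = 0.2085, seed = 3)   # 5-cell kernel
  st <- simulate_climate_layers(cfg, seed = 3)
  f <- st$layers[[1]]$values
  # correlogram decays with lag; lag 0 is exactly 1
  lag_cor <- function(k) cor(as.vector(f[1:(40 - k), ]),
                             as.vector(f[(1 + k):40, ]))
  expect_equal(lag_cor(0), 1)
  expect_gt(lag_cor(2), lag_cor(8))
  expect_gt(lag_cor(8), lag_cor(20))
  # distinct seeds give distinct fields
  st2 <- simulate_climate_layers(cfg, seed = 4)
  expect_false(identical(st$layers[[1]]$values, st2$layers[[1]]$values))
  # min-max rescaling hits the declared bioclim-like range exactly
  rng <- bioclim_ranges()[1, ]
  expect_equal(range(f), c(rng$lo, rng$hi))
})

test_that("Brownian optima match the BM closed forms", {
  phy <- ape::read.tree(text = "(A:1,B:1);")
  # sigma2 -> 0+ degenerates to the root state
  x0 <- evolve_niche_optima(phy, 3, 1e-12, root_state = 5, seed = 1)
  expect_equal(as.vector(x0), rep(5, 6), tolerance = 1e-4)
  expect_error(evolve_niche_optima(phy, 1, 0), "sigma2")

  # Var(tip difference) = 2 sigma2 T, using variables as replicates
  s2 <- 0.7
  x <- evolve_niche_optima(phy, 2000, s2, 0, seed = 2)
  expect_equal(var(x["A", ] - x["B", ]), 2 * s2 * 1, tolerance = 0.1)

  # Cov(two tips) = sigma2 * shared path length
  phy3 <- ape::read.tree(text = "((A:1,B:1):2,C:3);")
  x <- evolve_niche_optima(phy3, 4000, s2, 0, seed = 3)
  expect_equal(cov(x["A", ], x["B", ]), s2 * 2, tolerance = 0.15)
  expect_lt(abs(cov(x["A", ], x["C", ])), 0.15)
})

test_that("niche-derived suitability matches its closed form", {
  st <- small_stack(n_layers = 2, seed = 5)
  flat <- enm_raster(matrix(3, st$spec$n_rows, st$spec$n_cols), st$spec, "flat")
  st_flat <- raster_stack(list(flat))
  u <- suitability_from_niche(niche_spec(c(flat = 3), 1), st_flat)
  expect_equal(max(abs(u$values - 1 / sum(st_flat$valid))), 0)

  # tau -> infinity flattens any surface
  ns <- niche_spec(setNames(c(10, 20), names(st$layers)), 1e9)
  u2 <- suitability_from_niche(ns, st)
  expect_equal(diff(range(u2$values[st$valid])), 0, tolerance = 1e-12)

  # argmax cell minimizes the weighted squared deviation (brute force)
  ns <- niche_spec(setNames(c(12, 9), names(st$layers)), c(2, 5))
  s <- suitability_from_niche(ns, st)
  score <- (st$layers[[1]]$values - 12)^2 / 2^2 +
           (st$layers[[2]]$values - 9)^2 / 5^2
  score[!st$valid] <- Inf
  expect_equal(which.max(s$values), which.min(score))
})

test_that("occurrence sampling follows the surface weights", {
  spec <- tiny_spec(2, 3)
  w <- matrix(c(0.05, 0.1, 0.2, 0.25, 0.15, 0.25), 2, 3)
  surf <- suitability_surface(w, spec, matrix(TRUE, 2, 3), "s")
  # point mass: the single positive cell is always drawn
  pm <- suitability_surface(matrix(c(0, 0, 1, 0, 0, 0), 2, 3), spec,
                            matrix(TRUE, 2, 3), "pm")
  expect_equal(sample_occurrences(pm, 1, seed = 1)$cells,
               which(pm$values > 0))
  # same seed, same set; n too large errors
  expect_identical(sample_occurrences(surf, 4, seed = 7)$cells,
                   sample_occurrences(surf, 4, seed = 7)$cells)
  expect_error(sample_occurrences(pm, 2, seed = 1), "exceeds")
  # single-draw frequencies match the weights (chi-square, alpha = 0.01)
  draws <- vapply(1:10000, function(s)
    sample_occurrences(surf, 1, seed = s)$cells, integer(1))
  obs <- tabulate(draws, nbins = 6)
  expect_gt(chisq.test(obs, p = as.vector(w))$p.value, 0.01)
})

test_that("generated datasets are valid, truthful, and byte-stable", {
  cfg <- sim_config(n_taxa = 6, n_clades = 2, n_layers = 3, n_rows = 30,
                    n_cols = 30, n_points = 10, seed = 21)
  d1 <- withr::local_tempdir()
  ds <- make_dataset(cfg, d1)
  # every artifact passes the package's own readers/validators
  st <- read_layer_stack(d1)
  expect_length(st$layers, 3)
  phy <- read_newick(ds$paths$tree)
  occ <- read_occurrences(ds$paths$occurrences, st$spec)
  expect_length(occ, 6)
  expect_true(all(attr(occ, "n_unique") == 10))
  cl <- read_clade_map(ds$paths$clades, phy)   # monophyly checked inside
  expect_equal(sort(unique(unname(cl))), c("ruficollis", "schisticeps"))
  expect_true(file.exists(ds$paths$truth))
  # rerun with the same config is byte-identical
  d2 <- withr::local_tempdir()
  make_dataset(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  expect_error(sim_config(n_points = 9), "minimum of 10|>= 10")
})
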