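test_that("clade disparity matches hand computations", {
  v <- c(a = 0, b = 2)
  expect_equal(clade_disparity(v), 4)            # one pair, squared diff 4
  expect_equal(clade_disparity(v, metric = "euclidean"), 2)
  expect_equal(clade_disparity(c(x = 5)), 0)     # single taxon
  expect_equal(clade_disparity(c(a = 3, b = 3, c = 3)), 0)
  vv <- c(a = 0, b = 1, c = 10)
  expect_equal(clade_disparity(vv), mean(c(1, 100, 81)))
  expect_equal(clade_disparity(vv, taxa = c("a", "b")), 1)
  expect_error(clade_disparity(vv, taxa = "zz"), "unknown")
})

test_that("the DTT curve is anchored at 1 (root) and 0 (tips)", {
  for (s in 1:5) {
    phy <- simulate_yule_tree(10, seed = 700 + s)
    x <- withr::with_seed(710 + s, setNames(rnorm(10), phy$tip.label))
    cv <- relative_disparity_curve(phy, x)
    expect_equal(cv$disparity[1], 1)
    expect_equal(cv$times[1], 0)
    expect_equal(cv$disparity[length(cv$disparity)], 0)
    expect_equal(cv$times[length(cv$times)], 1)
    expect_true(all(diff(cv$times) > 0))
  }
  phy <- simulate_yule_tree(5, seed = 1)
  expect_error(relative_disparity_curve(
    phy, setNames(rep(1, 5), phy$tip.label)), "degenerate")
})

test_that("a 4-tip balanced tree matches the hand-enumerated curve", {
  phy <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  x <- c(A = 0, B = 1, C = 10, D = 11)
  cv <- relative_disparity_curve(phy, x)
  total <- mean(c(1, 100, 121, 81, 100, 1))     # all six pairs
  expect_equal(cv$times, c(0, 0.5, 1))
  # at t = 0.5+ both cherries are alive: mean of their relative disparities
  expect_equal(cv$disparity, c(1, mean(c(1, 1)) / total, 0))
})

test_that("the curve is invariant under affine transformation of tip values", {
  phy <- simulate_yule_tree(12, seed = 720)
  x <- withr::with_seed(721, setNames(rnorm(12), phy$tip.label))
  cv <- relative_disparity_curve(phy, x)
  cv2 <- relative_disparity_curve(phy, 3.7 * x - 11)
  expect_equal(cv2$disparity, cv$disparity, tolerance = 1e-12)
})

test_that("the curve matches the brute-force crossing-lineage oracle", {
  for (s in 1:25) {
    phy <- simulate_yule_tree(10, seed = 730 + s)
    x <- withr::with_seed(760 + s, setNames(rnorm(10), phy$tip.label))
    cv <- relative_disparity_curve(phy, x)
    oracle <- dtt_oracle(phy, x)
    expect_equal(cv$times, oracle$times, tolerance = 1e-12)
    expect_equal(cv$disparity, oracle$disparity, tolerance = 1e-10)
  }
})

test_that("the BM null is seeded, anchored, and envelops its median", {
  phy <- simulate_yule_tree(12, seed = 740)
  x <- withr::with_seed(741, setNames(rnorm(12), phy$tip.label))
  nul <- simulate_bm_null(phy, x, n_sim = 40, seed = 5)
  expect_identical(nul$curves,
                   simulate_bm_null(phy, x, n_sim = 40, seed = 5)$curves)
  expect_true(all(nul$curves[, 1] == 1))                  # every curve starts at 1
  expect_true(all(nul$curves[, ncol(nul$curves)] == 0))   # and ends at 0
  lo <- apply(nul$curves, 2, min); hi <- apply(nul$curves, 2, max)
  expect_true(all(nul$median >= lo & nul$median <= hi))
})

test_that("MDI is the trapezoid area between observed and null median", {
  phy <- simulate_yule_tree(10, seed = 750)
  x <- withr::with_seed(751, setNames(rnorm(10), phy$tip.label))
  obs <- relative_disparity_curve(phy, x)
  # observed vs itself -> 0
  expect_equal(mdi(obs, obs$disparity), 0)
  # constant offset integrates to the offset
  expect_equal(mdi(obs, obs$disparity - 0.3), 0.3, tolerance = 1e-12)
  # piecewise-linear toy curves, hand-integrated
  toy <- structure(list(times = c(0, 0.5, 1), disparity = c(1, 0.8, 0)),
                   class = "dtt_curve")
  nullmed <- c(1, 0.4, 0)
  # trapezoid of diff (0, .4, 0): 0.5*(0+.4)/2 + 0.5*(.4+0)/2 = 0.2
  expect_equal(mdi(toy, nullmed), 0.2)
  expect_error(mdi(toy, c(1, 0)), "length")
  nul <- simulate_bm_null(phy, x, 10, seed = 1)
  sub <- nul; sub$times <- nul$times + 0.01
  expect_error(mdi(obs, sub), "time grids")
})

test_that("clade-wise DTT equals the direct subtree analysis", {
  phy <- simulate_yule_tree(14, seed = 752)
  x <- withr::with_seed(753, setNames(rnorm(14), phy$tip.label))
  clades <- assign_clades(phy, 2)
  res <- clade_dtt(phy, clades, x, n_sim = 30, seed = 9)
  for (cl in res$clade) {
    members <- names(clades)[clades == cl]
    if (length(members) < 3) next
    sub <- ape::extract.clade(phy, ape::getMRCA(phy, members))
    obs <- relative_disparity_curve(sub, x[sub$tip.label])
    nul <- simulate_bm_null(sub, x[sub$tip.label], 30,
                            seed = derive_seed(9, paste0("clade:", cl)))
    expect_equal(res$mdi[res$clade == cl], mdi(obs, nul))
  }
  # the whole tree as a single clade reproduces the global analysis
  whole <- setNames(rep("all", 14), phy$tip.label)
  res_all <- clade_dtt(phy, whole, x, n_sim = 30, seed = 11)
  obs <- relative_disparity_curve(phy, x)
  nul <- simulate_bm_null(phy, x, 30,
                          seed = derive_seed(11, "clade:all"))
  expect_equal(res_all$mdi, mdi(obs, nul))
  # undersized clades are skipped with a warning
  phy6 <- ape::read.tree(
    text = "((A:2,B:2):1,((C:1,D:1):1,(E:1,F:1):1):1);")
  x6 <- c(A = 0, B = 1, C = 5, D = 6, E = 2, F = 9)
  tiny <- c(A = "pair", B = "pair", C = "rest", D = "rest",
            E = "rest", F = "rest")
  expect_warning(r2 <- clade_dtt(phy6, tiny, x6, n_sim = 10, seed = 1),
                 "skipped")
  expect_true(is.na(r2$mdi[r2$clade == "pair"]))
  expect_false(is.na(r2$mdi[r2$clade == "rest"]))
})

test_that("dtt_pipeline composes the stages it wraps", {
  spec <- tiny_spec(1, 6)
  layer <- enm_raster(matrix(c(1, 3, 5, 7, 9, 11), 1, 6), spec, "bio01")
  phy <- simulate_yule_tree(4, seed = 754)
  profs <- lapply(setNames(seq_len(4), phy$tip.label), function(i) {
    w <- matrix(0, 1, 6); w[1, i] <- 0.7; w[1, i + 1] <- 0.3
    compute_pno(suitability_surface(w, spec, matrix(TRUE, 1, 6), "s"),
                layer, n_bins = 6, range = c(0, 12))
  })
  out <- dtt_pipeline(phy, list(bio01 = profs), n_sim = 25, seed = 3)
  expect_equal(nrow(out$table), 1)
  tips <- vapply(profs, pno_weighted_mean, numeric(1))
  obs <- relative_disparity_curve(phy, tips)
  nul <- simulate_bm_null(phy, tips, 25, seed = derive_seed(3, "dtt:bio01"))
  expect_equal(out$table$mdi, mdi(obs, nul))
  # deterministic given the seed
  out2 <- dtt_pipeline(phy, list(bio01 = profs), n_sim = 25, seed = 3)
  expect_identical(out$table, out2$table)
})
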