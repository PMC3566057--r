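test_that("minimum convex polygon is the hull with the shoelace area", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  hull <- minimum_convex_polygon(sq)
  expect_equal(hull$area, 1)
  expect_equal(nrow(hull$vertices), 4)
  # interior points do not change the hull
  tri <- rbind(c(0, 0), c(4, 0), c(0, 4), c(1, 1))
  h2 <- minimum_convex_polygon(tri)
  expect_equal(h2$area, 8)
  expect_equal(nrow(h2$vertices), 3)
  expect_true(all(in_polygon(tri[, 1], tri[, 2], h2)))
  expect_error(minimum_convex_polygon(cbind(0:4, 0:4)), "collinear")
  expect_error(minimum_convex_polygon(rbind(c(0, 0), c(1, 1))), "3")
})

test_that("background sampling is uniform within the polygon and seeded", {
  st <- small_stack(n_layers = 1, n_rows = 6, n_cols = 6, seed = 2)
  poly <- minimum_convex_polygon(rbind(
    cell_center(1, st$spec) + c(-1, 1), cell_center(36, st$spec) + c(1, -1),
    cell_center(6, st$spec) + c(1, 1), cell_center(31, st$spec) - c(1, -1)))
  bg <- build_background(poly, st, 10, seed = 1)
  expect_length(bg$cells, 10)
  expect_identical(bg$cells, build_background(poly, st, 10, seed = 1)$cells)
  expect_warning(build_background(poly, st, 1e5, seed = 1), "using all")
  # single-cell draws over many seeds are uniform over eligible cells
  draws <- vapply(1:3000, function(s)
    build_background(poly, st, 1, seed = s)$cells, integer(1))
  obs <- table(factor(draws, levels = bg$eligible))
  expect_gt(chisq.test(obs)$p.value, 0.01)
})

test_that("train/test split honors the 80/20 convention", {
  sp <- split_train_test(1:10, 0.8, seed = 1)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$test), 1:10)
  sp2 <- split_train_test(1:2, 0.8, seed = 1)
  expect_length(sp2$train, 1)
  expect_error(split_train_test(1, 0.8), "at least 2")
})

test_that("the Gibbs model finds no signal in uniform presences", {
  st <- small_stack(n_layers = 2, seed = 6)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 400, seed = 2)
  feats <- build_features(st, bg)
  pres <- withr::with_seed(3, sample(bg$cells, 60))
  mod <- fit_maxent(pres, bg, feats)
  expect_true(all(abs(mod$lambda) <= 0.05))
  surf <- predict_raw(mod, feats)
  n_cells <- sum(st$valid)
  expect_lt(max(abs(surf$values[st$valid] - 1 / n_cells)), 2 / n_cells)
  # objective is non-decreasing across iterations
  expect_true(all(diff(mod$objective) >= -1e-10))
})

test_that("presences concentrated at high values of a variable yield positive weight", {
  st <- small_stack(n_layers = 1, seed = 8)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 500, seed = 3)
  feats <- build_features(st, bg)
  v <- st$layers[[1]]$values[feats$cells]
  pres <- feats$cells[v >= quantile(v, 0.9)][1:20]
  mod <- fit_maxent(pres, bg, feats)
  expect_gt(mod$lambda[paste0("lin_", names(st$layers)[1])], 0)
})

test_that("RAW prediction is normalized and rank-faithful", {
  st <- small_stack(n_layers = 2, seed = 9)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 300, seed = 4)
  feats <- build_features(st, bg)
  # lambda = 0 -> uniform over valid cells
  mod0 <- fit_maxent(bg$cells[1:5], bg, feats, beta = 1e6, max_iter = 1)
  expect_true(all(mod0$lambda == 0))
  s0 <- predict_raw(mod0, feats)
  expect_equal(unique(as.vector(s0$values[st$valid])), 1 / sum(st$valid))
  # a fitted surface sums to 1 and ranks cells exactly as eta does
  pres <- withr::with_seed(5, sample(feats$cells, 30))
  mod <- fit_maxent(pres, bg, feats)
  surf <- predict_raw(mod, feats)
  expect_equal(sum(surf$values), 1, tolerance = 1e-12)
  eta <- as.vector(feats$X %*% mod$lambda)
  idx <- withr::with_seed(6, sample(length(feats$cells), 20))
  for (i in idx[-1])
    expect_equal(surf$values[feats$cells[idx[1]]] > surf$values[feats$cells[i]],
                 eta[idx[1]] > eta[i])
})

test_that("rank-based AUC behaves at its three anchors", {
  spec <- tiny_spec(2, 5)
  v <- matrix(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), 2, 5)
  surf <- suitability_surface(v, spec, matrix(TRUE, 2, 5), "s")
  expect_equal(evaluate_auc(surf, 1:3, 4:10), 1)        # perfect separation
  flat <- suitability_surface(matrix(1, 2, 5), spec, matrix(TRUE, 2, 5), "f")
  expect_equal(evaluate_auc(flat, 1:3, 4:10), 0.5)      # all tied, mid-ranks
  # presences drawn from the background itself give AUC ~ 0.5 on average
  aucs <- withr::with_seed(11, vapply(1:200, function(i) {
    pres <- sample(1:10, 3)
    evaluate_auc(surf, pres, 1:10)
  }, numeric(1)))
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
  expect_error(evaluate_auc(surf, integer(0), 1:10), "test presence")
  expect_error(evaluate_auc(surf, 1, integer(0)), "background")
})

test_that("cross-validation averages fold surfaces into a unit-mass model", {
  st <- small_stack(n_layers = 2, seed = 12)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 300, seed = 5)
  feats <- build_features(st, bg)
  ns <- niche_spec(setNames(c(12, 8), names(st$layers)), c(4, 4))
  occ <- sample_occurrences(suitability_from_niche(ns, st), 10, seed = 6)
  cv <- crossvalidate(occ$cells, bg, feats, k = 10, seed = 7)
  expect_equal(cv$n_fits, 10)                 # leave-one-out runs n fits
  expect_length(cv$fold_auc, 10)
  expect_equal(sum(cv$surface$values), 1, tolerance = 1e-12)
  expect_error(crossvalidate(occ$cells, bg, feats, k = 11), "folds")
})

test_that("fitted models separate presences from background (AUC > 0.5)", {
  st <- small_stack(n_layers = 2, n_rows = 30, n_cols = 30, seed = 13)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 500, seed = 8)
  feats <- build_features(st, bg)
  ns <- niche_spec(setNames(c(14, 9), names(st$layers)), c(3, 3))
  truth <- suitability_from_niche(ns, st)
  hits <- vapply(1:20, function(s) {
    occ <- sample_occurrences(truth, 50, seed = 100 + s)
    sp <- split_train_test(occ$cells, 0.8, seed = s)
    mod <- fit_maxent(sp$train, bg, feats)
    evaluate_auc(predict_raw(mod, feats), sp$test, bg$cells) > 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("permutation contributions sum to 100 and isolate the signal", {
  st <- small_stack(n_layers = 3, n_rows = 30, n_cols = 30, seed = 14)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 500, seed = 9)
  feats <- build_features(st, bg)
  # truth depends on variable 1 only
  ns <- niche_spec(setNames(13, names(st$layers)[1]), 2)
  occ <- sample_occurrences(suitability_from_niche(ns, st), 80, seed = 10)
  mod <- fit_maxent(occ$cells, bg, feats)
  contrib <- variable_contribution(mod, feats, occ$cells, bg,
                                   n_permutations = 20, seed = 11)
  expect_equal(sum(contrib), 100, tolerance = 0.01)
  expect_gt(contrib[names(st$layers)[1]], 90)
  # a variable with zero weights contributes exactly 0
  mod0 <- mod
  cols <- paste0(c("lin_", "quad_"), names(st$layers)[2])
  mod0$lambda[cols] <- 0
  c0 <- variable_contribution(mod0, feats, occ$cells, bg,
                              n_permutations = 2, seed = 12)
  expect_equal(unname(c0[names(st$layers)[2]]), 0)
})

test_that("top-variable selection ranks by mean contribution with alphabetical ties", {
  reports <- list(
    list(contributions = c(alpha = 50, beta = 30, gamma = 20)),
    list(contributions = c(alpha = 10, beta = 60, gamma = 30)),
    list(contributions = c(alpha = 30, beta = 30, gamma = 40)))
  expect_identical(select_top_variables(reports, 2), c("beta", "alpha"))
  tied <- list(list(contributions = c(b = 50, c = 25, a = 25)))
  expect_message(sel <- select_top_variables(tied, 2), "alphabetically")
  expect_identical(sel, c("b", "a"))
  expect_error(select_top_variables(reports, 4), "exceeds")
})

test_that("minimum-training-presence binarization matches hand enumeration", {
  spec <- tiny_spec(3, 3)
  w <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  surf <- suitability_surface(w, spec, matrix(TRUE, 3, 3), "s")
  b <- binarize_mtp(surf, training_cells = c(4, 6))
  expect_equal(b$threshold, surf$values[4])   # min over presences
  expect_identical(as.vector(b$values), as.vector(w >= 4))
  # all presences at the max cell leave only argmax cells true
  b2 <- binarize_mtp(surf, 9)
  expect_equal(which(b2$values), 9L)
})

test_that("richness stacking counts species per cell", {
  spec <- tiny_spec(2, 2)
  mk <- function(v) binarize_mtp(
    suitability_surface(matrix(v, 2, 2), spec, matrix(TRUE, 2, 2), "s"),
    which.max(matrix(v, 2, 2)))
  b1 <- mk(c(1, 0.1, 0.1, 0.1)); b2 <- mk(c(0.1, 1, 0.1, 0.1))
  same <- stack_richness(list(b1, b1))
  expect_setequal(unique(as.vector(same$values)), c(0, 2))
  disj <- stack_richness(list(b1, b2))
  expect_lte(max(disj$values), 1)
  # random set equals the brute-force per-cell sum
  bs <- lapply(1:4, function(s) mk(withr::with_seed(s, runif(4))))
  rich <- stack_richness(bs)
  brute <- Reduce(`+`, lapply(bs, function(b) b$values + 0))
  expect_equal(rich$values, brute)
})

test_that("species below the 10-point minimum are rejected", {
  st <- small_stack(n_layers = 1, seed = 15)
  poly <- minimum_convex_polygon(cell_center(which(st$valid), st$spec))
  bg <- build_background(poly, st, 200, seed = 13)
  feats <- build_features(st, bg)
  occ <- occurrence_set("rare", feats$cells[1:9], st$spec)
  expect_error(fit_species_enm(occ, bg, feats), "minimum of 10")
})
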