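## Presence-background ecological niche models.
##
## The model is a Gibbs (exponential-family) distribution over the valid
## cells of the study area: P(cell i) proportional to exp(lambda . f(i)),
## with standardized linear and quadratic features of each climate variable
## and an L1 penalty on the weights.  The fitted surface is exported in the
## "RAW" convention: nonnegative weights summing to 1 over valid cells, a
## probability distribution over geography that all downstream overlap and
## niche-occupancy math consumes.

#' Construct a RAW suitability surface
#'
#' @param values nonnegative weight matrix (grid shape); will be normalized
#'   to unit mass over valid cells.  Invalid cells are set to exactly 0.
#' @param spec a \code{\link{grid_spec}}.
#' @param valid logical validity mask (grid shape).
#' @param species species label.
#' @return an object of class \code{c("suitability", "enm_raster")}.
#' @export
suitability_surface <- function(values, spec, valid, species = "species") {
  values <- as.matrix(values)
  stopifnot(inherits(spec, "grid_spec"),
            nrow(values) == spec$n_rows, ncol(values) == spec$n_cols,
            identical(dim(valid), dim(values)))
  values[!valid] <- 0
  w <- values[valid]
  if (any(!is.finite(w)) || any(w < 0))
    abort("suitability weights must be finite and nonnegative")
  tot <- sum(w)
  if (!any(valid) || tot <= 0)
    abort("suitability surface has no positive mass on valid cells")
  values <- values / tot
  stopifnot(abs(sum(values[valid]) - 1) <= 1e-9)
  structure(list(values = values, spec = spec, valid = valid,
                 name = species),
            class = c("suitability", "enm_raster"))
}

#' Minimum convex polygon around occurrence points
#'
#' The convex hull of the pooled occurrence points of all species,
#' delimiting the region from which background cells are drawn.
#'
#' @param points two-column matrix of (lon, lat) coordinates (>= 3
#'   non-collinear points).
#' @return an object of class \code{"mcp"}: hull vertices
#'   (counter-clockwise) and area (squared degrees, shoelace formula).
#' @export
minimum_convex_polygon <- function(points) {
  points <- as.matrix(points)
  points <- unique(points)
  if (nrow(points) < 3)
    abort("need at least 3 distinct points for a convex polygon")
  idx <- grDevices::chull(points[, 1], points[, 2])
  hull <- points[idx, , drop = FALSE]
  ## shoelace signed area; chull returns clockwise order, flip to ccw
  x <- hull[, 1]; y <- hull[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) / 2 < 1e-12 * max(1, max(abs(points))^2))
    abort("occurrence points are collinear; cannot build a convex polygon")
  if (area2 < 0) { hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE] }
  structure(list(vertices = hull, area = abs(area2) / 2), class = "mcp")
}

#' Test points for inclusion in a minimum convex polygon
#'
#' Boundary points count as inside.
#'
#' @param x,y point coordinates.
#' @param polygon an \code{\link{minimum_convex_polygon}} result.
#' @return logical vector.
#' @export
in_polygon <- function(x, y, polygon) {
  v <- polygon$vertices
  n <- nrow(v)
  eps <- 1e-9 * max(1, max(abs(v)))
  inside <- rep(TRUE, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cross <- (v[j, 1] - v[i, 1]) * (y - v[i, 2]) -
             (v[j, 2] - v[i, 2]) * (x - v[i, 1])
    inside <- inside & (cross >= -eps)   # ccw orientation
  }
  inside
}

#' Sample background cells inside the study polygon
#'
#' Uniform sample, without replacement, among valid cells of the stack
#' whose centers fall inside the polygon.  If fewer eligible cells exist
#' than requested, all of them are used with a warning.
#'
#' @param polygon the minimum convex polygon of all occurrences.
#' @param stack the climate \code{\link{raster_stack}}.
#' @param n_background requested sample size (default 10000).
#' @param seed RNG seed.
#' @return an object of class \code{"background_sample"} with elements
#'   \code{cells} (column-major indices), \code{eligible} and
#'   \code{polygon}.
#' @export
build_background <- function(polygon, stack, n_background = 10000, seed = 1) {
  stopifnot(inherits(polygon, "mcp"), inherits(stack, "raster_stack"))
  if (n_background < 1) abort("n_background must be >= 1")
  cand <- which(stack$valid)
  ctr <- cell_center(cand, stack$spec)
  eligible <- cand[in_polygon(ctr[, "lon"], ctr[, "lat"], polygon)]
  if (length(eligible) == 0) abort("no valid cells inside the polygon")
  if (n_background >= length(eligible)) {
    if (n_background > length(eligible))
      warning("only ", length(eligible), " eligible cells for ",
              n_background, " requested background points; using all",
              call. = FALSE)
    cells <- eligible
  } else {
    cells <- with_seed(seed,
      sort(eligible[sample.int(length(eligible), n_background)]))
  }
  structure(list(cells = cells, eligible = eligible, polygon = polygon),
            class = "background_sample")
}

#' Split occurrence cells into training and testing sets
#'
#' @param cells occurrence cell indices (n >= 2).
#' @param fraction training fraction in (0, 1); default 0.8.
#' @param seed RNG seed.
#' @return list with integer vectors \code{train} and \code{test}
#'   (disjoint, union = input); \code{|train| = round(fraction * n)},
#'   clamped so both parts are non-empty.
#' @export
split_train_test <- function(cells, fraction = 0.8, seed = 1) {
  n <- length(cells)
  if (n < 2) abort("need at least 2 points to split")
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  n_train <- min(max(round(fraction * n), 1), n - 1)
  tr <- with_seed(seed, sort(sample.int(n, n_train)))
  list(train = cells[tr], test = cells[-tr])
}

#' Build the standardized feature matrix of a climate stack
#'
#' Features are the standardized value of each variable (z) and its square
#' (z^2), with standardization means/SDs computed on the background sample
#' only.  Variables with zero variance on the background are dropped with a
#' warning.
#'
#' @param stack a \code{\link{raster_stack}}.
#' @param background a \code{\link{build_background}} result.
#' @return an object of class \code{"feature_matrix"}: \code{X} (rows =
#'   valid cells, columns = \code{lin_<var>}, \code{quad_<var>}),
#'   \code{cells}, \code{vars}, \code{means}, \code{sds}, \code{spec},
#'   \code{valid}.
#' @export
build_features <- function(stack, background) {
  stopifnot(inherits(stack, "raster_stack"),
            inherits(background, "background_sample"))
  cells <- which(stack$valid)
  raw <- vapply(stack$layers, function(l) l$values[cells],
                numeric(length(cells)))
  bg_rows <- match(background$cells, cells)
  if (anyNA(bg_rows)) abort("background contains invalid cells")
  m <- colMeans(raw[bg_rows, , drop = FALSE])
  s <- apply(raw[bg_rows, , drop = FALSE], 2, stats::sd)
  keep <- s > 0
  if (!all(keep))
    warning("dropping zero-variance variable(s) on background: ",
            paste(names(s)[!keep], collapse = ", "), call. = FALSE)
  if (!any(keep)) abort("no variable has variance on the background")
  vars <- colnames(raw)[keep]
  z <- sweep(sweep(raw[, keep, drop = FALSE], 2, m[keep]), 2, s[keep], "/")
  X <- cbind(z, z^2)
  colnames(X) <- c(paste0("lin_", vars), paste0("quad_", vars))
  structure(list(X = X, cells = cells, vars = vars,
                 means = m[keep], sds = s[keep],
                 spec = stack$spec, valid = stack$valid),
            class = "feature_matrix")
}

## log-sum-exp, guarded against overflow
lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' Fit the penalized Gibbs presence-background model
#'
#' Maximizes the L1-penalized presence log-likelihood
#' \deqn{\ell(\lambda) = \bar{f}_{pres} \cdot \lambda -
#'       \log \sum_{j \in background} e^{\lambda \cdot f_j} -
#'       \beta \sum_k |\lambda_k|}
#' by proximal gradient ascent (soft-thresholding) with step halving, so
#' the penalized objective is non-decreasing across iterations.
#' Convergence is declared when the subgradient norm drops below
#' \code{tol}; otherwise the iteration cap is reported in the model.
#'
#' @param presence_cells training presence cell indices (>= 2).
#' @param background a \code{\link{build_background}} result.
#' @param features a \code{\link{build_features}} result.
#' @param beta L1 regularization strength (default 0.1).
#' @param max_iter iteration cap (default 5000).
#' @param tol subgradient max-norm convergence tolerance.
#' @return an object of class \code{"enm_model"}: \code{lambda} (named
#'   weights), \code{beta}, \code{objective} trace, \code{iterations},
#'   \code{converged}, \code{n_presence}, plus the feature
#'   standardization metadata.
#' @export
fit_maxent <- function(presence_cells, background, features, beta = 0.1,
                       max_iter = 5000, tol = 1e-6) {
  stopifnot(inherits(features, "feature_matrix"))
  pr <- match(presence_cells, features$cells)
  if (anyNA(pr)) abort("presence on an invalid cell: ",
                       paste(presence_cells[is.na(pr)], collapse = ", "))
  if (length(pr) < 2) abort("need at least 2 training presences")
  bg <- match(background$cells, features$cells)
  Xb <- features$X[bg, , drop = FALSE]
  fbar <- colMeans(features$X[pr, , drop = FALSE])
  p <- ncol(Xb)
  lambda <- numeric(p)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  smooth_obj <- function(l) sum(fbar * l) - lse(Xb %*% l)
  pen_obj <- function(l) smooth_obj(l) - beta * sum(abs(l))
  obj <- pen_obj(lambda)
  trace <- obj
  step <- 1
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- as.vector(Xb %*% lambda)
    q <- exp(eta - max(eta)); q <- q / sum(q)
    grad <- fbar - as.vector(crossprod(Xb, q))
    ## subgradient norm of the penalized objective
    sg <- ifelse(lambda != 0, grad - beta * sign(lambda),
                 soft(grad, beta))
    if (max(abs(sg)) < tol) { converged <- TRUE; break }
    repeat {
      cand <- soft(lambda + step * grad, step * beta)
      cobj <- pen_obj(cand)
      if (is.finite(cobj) && cobj >= obj - 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) break
    lambda <- cand
    obj <- cobj
    trace <- c(trace, obj)
    step <- step * 2
  }
  if (!is.finite(obj)) abort("non-finite objective in fit_maxent")
  if (!converged)
    message("fit_maxent: iteration cap ", max_iter,
            " reached (subgradient norm ", signif(max(abs(sg)), 3), ")")
  names(lambda) <- colnames(features$X)
  structure(list(lambda = lambda, beta = beta, objective = trace,
                 iterations = iter, converged = converged,
                 n_presence = length(pr),
                 vars = features$vars, means = features$means,
                 sds = features$sds),
            class = "enm_model")
}

#' Predict the RAW suitability surface of a fitted model
#'
#' @param model an \code{\link{fit_maxent}} result.
#' @param features the \code{\link{build_features}} object used at fit
#'   time (or one with identical columns).
#' @param species label for the surface.
#' @return a \code{\link{suitability_surface}}: \code{p_i} proportional to
#'   \code{exp(lambda . f(i))} over valid cells, normalized to unit mass.
#' @export
predict_raw <- function(model, features, species = "species") {
  stopifnot(inherits(model, "enm_model"),
            inherits(features, "feature_matrix"))
  if (!identical(names(model$lambda), colnames(features$X)))
    abort("feature columns do not match the fitted model")
  eta <- as.vector(features$X %*% model$lambda)
  w <- exp(eta - max(eta))
  vals <- matrix(0, features$spec$n_rows, features$spec$n_cols)
  vals[features$cells] <- w
  suitability_surface(vals, features$spec, features$valid, species = species)
}

#' Rank-based AUC of a suitability surface
#'
#' Mann-Whitney AUC of presence-cell suitabilities against background-cell
#' suitabilities, with mid-ranks for ties: the probability that a random
#' presence cell outranks a random background cell.
#'
#' @param surface a \code{\link{suitability_surface}}.
#' @param test_cells presence cell indices (>= 1).
#' @param background_cells background cell indices (>= 1).
#' @return AUC in [0, 1].
#' @export
evaluate_auc <- function(surface, test_cells, background_cells) {
  stopifnot(inherits(surface, "suitability"))
  if (length(test_cells) < 1) abort("need at least 1 test presence")
  if (length(background_cells) < 1) abort("empty background")
  sp <- surface$values[test_cells]
  sb <- surface$values[background_cells]
  r <- rank(c(sp, sb))
  np <- length(sp); nb <- length(sb)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' k-fold cross-validated model fit
#'
#' Partitions the occurrence cells into k folds; fits on the training folds
#' and evaluates AUC on each held-out fold; the final surface is the
#' cell-wise mean of the fold surfaces renormalized to unit mass.
#'
#' @param cells occurrence cell indices.
#' @param background,features as in \code{\link{fit_maxent}}.
#' @param k number of folds (2 <= k <= n); \code{k = n} is leave-one-out.
#' @param beta,max_iter passed to \code{\link{fit_maxent}}.
#' @param seed RNG seed for the fold assignment.
#' @param species label for the averaged surface.
#' @return list: \code{surface} (averaged), \code{auc} (mean held-out
#'   AUC), \code{fold_auc}, \code{k}, \code{n_fits}.
#' @export
crossvalidate <- function(cells, background, features, k,
                          beta = 0.1, max_iter = 5000, seed = 1,
                          species = "species") {
  n <- length(cells)
  if (k < 2) abort("k must be >= 2")
  if (n < k) abort("more folds than occurrence points")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  acc <- NULL
  fold_auc <- numeric(k)
  for (f in seq_len(k)) {
    train <- cells[fold != f]
    test <- cells[fold == f]
    mod <- fit_maxent(train, background, features, beta = beta,
                      max_iter = max_iter)
    surf <- predict_raw(mod, features, species = species)
    fold_auc[f] <- evaluate_auc(surf, test, background$cells)
    acc <- if (is.null(acc)) surf$values else acc + surf$values
  }
  surface <- suitability_surface(acc / k, features$spec, features$valid,
                                 species = species)
  list(surface = surface, auc = mean(fold_auc), fold_auc = fold_auc,
       k = k, n_fits = k)
}

#' Permutation importance of each climate variable
#'
#' For each variable, both of its feature columns are permuted together
#' across valid cells and the resulting drop in AUC (evaluated at the test
#' presences against the background) is averaged over permutations, floored
#' at 0, and normalized so contributions sum to 100.
#'
#' @param model a fitted \code{\link{fit_maxent}} model.
#' @param features the feature matrix used at fit time.
#' @param test_cells presence cells used for the AUC.
#' @param background the background sample.
#' @param n_permutations permutation replicates per variable.
#' @param seed RNG seed.
#' @return named numeric vector of percent contributions (sums to 100).
#' @export
variable_contribution <- function(model, features, test_cells, background,
                                  n_permutations = 5, seed = 1) {
  stopifnot(inherits(model, "enm_model"))
  surf <- predict_raw(model, features)
  auc0 <- evaluate_auc(surf, test_cells, background$cells)
  vars <- features$vars
  n_cells <- nrow(features$X)
  drops <- stats::setNames(numeric(length(vars)), vars)
  with_seed(seed, for (v in vars) {
    cols <- c(paste0("lin_", v), paste0("quad_", v))
    if (all(model$lambda[cols] == 0)) next   # absent from the model
    d <- 0
    for (r in seq_len(n_permutations)) {
      perm <- sample.int(n_cells)
      Xp <- features$X
      Xp[, cols] <- Xp[perm, cols]
      fp <- features; fp$X <- Xp
      sp <- predict_raw(model, fp)
      d <- d + (auc0 - evaluate_auc(sp, test_cells, background$cells))
    }
    drops[v] <- max(d / n_permutations, 0)
  })
  tot <- sum(drops)
  if (tot <= 0) {
    warning("no variable shows positive permutation importance; ",
            "returning equal contributions", call. = FALSE)
    return(stats::setNames(rep(100 / length(vars), length(vars)), vars))
  }
  100 * drops / tot
}

#' Rank variables by mean contribution across species
#'
#' @param reports list of per-species evaluation reports, each with a
#'   named \code{contributions} vector.
#' @param n_keep number of variables to keep (default 10).
#' @return character vector of the top \code{n_keep} variable names,
#'   ranked by mean contribution; ties broken alphabetically (reported
#'   via a message).
#' @export
select_top_variables <- function(reports, n_keep = 10) {
  if (length(reports) < 1) abort("need at least one report")
  tab <- do.call(rbind, lapply(reports, `[[`, "contributions"))
  means <- colMeans(tab)
  if (n_keep > length(means))
    abort("n_keep = ", n_keep, " exceeds the ", length(means),
          " available variables")
  if (anyDuplicated(means))
    message("select_top_variables: tied mean contributions broken ",
            "alphabetically")
  ord <- order(-means, names(means))
  names(means)[ord][seq_len(n_keep)]
}

#' Binarize a surface at the minimum training presence threshold
#'
#' The threshold is the lowest predicted suitability at any training
#' presence cell; a cell is predicted present iff its suitability is at or
#' above the threshold.
#'
#' @param surface a \code{\link{suitability_surface}}.
#' @param training_cells training presence cell indices.
#' @return an object of class \code{"binary_surface"}: logical
#'   \code{values}, the \code{threshold}, \code{spec} and species name.
#' @export
binarize_mtp <- function(surface, training_cells) {
  stopifnot(inherits(surface, "suitability"))
  if (length(training_cells) < 1) abort("need at least 1 training presence")
  if (!all(surface$valid[training_cells]))
    abort("training presence on an invalid cell")
  thr <- min(surface$values[training_cells])
  structure(list(values = surface$valid & surface$values >= thr,
                 threshold = thr, spec = surface$spec,
                 name = surface$name),
            class = "binary_surface")
}

#' Species-richness raster from binary surfaces
#'
#' @param binaries list of co-registered \code{\link{binarize_mtp}}
#'   results.
#' @return an \code{\link{enm_raster}} counting, per cell, the species
#'   predicted present.
#' @export
stack_richness <- function(binaries) {
  if (length(binaries) < 1) abort("need at least one binary surface")
  stopifnot(all(vapply(binaries, inherits, logical(1), "binary_surface")))
  spec <- binaries[[1]]$spec
  for (b in binaries)
    if (!same_grid(spec, b$spec)) abort("binary surfaces not co-registered")
  acc <- Reduce(`+`, lapply(binaries, function(b) b$values * 1L))
  enm_raster(acc, spec, name = "richness")
}

#' Fit the full per-species niche model workflow
#'
#' Applies the study workflow for one species: reject species below the
#' 10-point minimum; leave-one-out cross-validation for species with up to
#' \code{cv_max_points} points, otherwise \code{replicates} re-seeded
#' 80/20 split fits averaged cell-wise; permutation variable contributions
#' from a final all-points fit.
#'
#' @param occ an \code{\link{occurrence_set}}.
#' @param background,features shared study-area background and features.
#' @param beta,max_iter model settings.
#' @param train_fraction training fraction for split replicates.
#' @param cv_max_points species at or below this count use leave-one-out
#'   cross-validation (default 12).
#' @param replicates number of re-seeded split replicates (default 20).
#' @param n_permutations permutations per variable for contributions.
#' @param min_points minimum spatially unique points (default 10).
#' @param seed RNG seed.
#' @return list: \code{surface} (averaged RAW surface), \code{report}
#'   (species, n_points, auc, method, replicates, contributions),
#'   \code{model} (final all-points fit).
#' @export
fit_species_enm <- function(occ, background, features, beta = 0.1,
                            max_iter = 5000, train_fraction = 0.8,
                            cv_max_points = 12, replicates = 20,
                            n_permutations = 5, min_points = 10, seed = 1) {
  stopifnot(inherits(occ, "occurrence_set"))
  n <- length(occ$cells)
  if (n < min_points)
    abort("species '", occ$species, "' has ", n, " spatially unique points; ",
          "models require a minimum of ", min_points)
  if (n <= cv_max_points) {
    cv <- crossvalidate(occ$cells, background, features, k = n,
                        beta = beta, max_iter = max_iter, seed = seed,
                        species = occ$species)
    surface <- cv$surface
    auc <- cv$auc
    method <- sprintf("loo-cv (k=%d)", n)
    n_rep <- cv$k
  } else {
    acc <- NULL
    aucs <- numeric(replicates)
    for (r in seq_len(replicates)) {
      sp <- split_train_test(occ$cells, train_fraction,
                             seed = derive_seed(seed, paste0("split", r)))
      mod <- fit_maxent(sp$train, background, features, beta = beta,
                        max_iter = max_iter)
      surf <- predict_raw(mod, features, species = occ$species)
      aucs[r] <- evaluate_auc(surf, sp$test, background$cells)
      acc <- if (is.null(acc)) surf$values else acc + surf$values
    }
    surface <- suitability_surface(acc / replicates, features$spec,
                                   features$valid, species = occ$species)
    auc <- mean(aucs)
    method <- sprintf("%d x %d/%d split", replicates,
                      round(100 * train_fraction),
                      round(100 * (1 - train_fraction)))
    n_rep <- replicates
  }
  final <- fit_maxent(occ$cells, background, features, beta = beta,
                      max_iter = max_iter)
  contrib <- variable_contribution(final, features, occ$cells, background,
                                   n_permutations = n_permutations,
                                   seed = derive_seed(seed, "perm"))
  list(surface = surface,
       report = list(species = occ$species, n_points = n, auc = auc,
                     method = method, replicates = n_rep,
                     contributions = contrib),
       model = final)
}
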