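## End-to-end orchestration: simulate (or load) inputs, fit the per-species
## niche models, compute overlap, PNO profiles, ancestral reconstructions
## and DTT/MDI, writing every stage's outputs in the package's exchange
## formats plus a deterministic manifest.  Each stage consumes and produces
## only those formats, so stages are independently re-runnable from R.

#' Build a pipeline configuration
#'
#' Defaults follow the study conditions the pipeline is designed around:
#' 80/20 training split averaged over 20 replicate runs (leave-one-out
#' cross-validation for species with up to 12 points), 10000 background
#' points, 10 retained variables, 50 PNO bins, 100 PNO draws and 1000 BM
#' null simulations.
#'
#' @param out_dir output directory.
#' @param inputs either a \code{\link{sim_config}} (inputs are simulated
#'   into \code{out_dir/inputs}) or a list with paths \code{layers} (dir
#'   or files), \code{tree}, \code{occurrences}, \code{clades}.
#' @param beta,max_iter,background_n,train_fraction,cv_max_points,replicates
#'   niche-model settings (see \code{\link{fit_species_enm}}).
#' @param n_permutations permutations per variable for contributions.
#' @param n_keep_variables variables retained for the downstream stages
#'   (default 10); if fewer than the number of layers, models are refit on
#'   the retained variables.
#' @param n_bins PNO bins (default 50).
#' @param n_draws PNO draws for the reconstruction (default 100).
#' @param n_sim BM null simulations (default 1000).
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param strict if TRUE, validation issues abort the run.
#' @return an object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir, inputs = sim_config(),
                            beta = 0.1, max_iter = 5000,
                            background_n = 10000, train_fraction = 0.8,
                            cv_max_points = 12, replicates = 20,
                            n_permutations = 5, n_keep_variables = 10,
                            n_bins = 50, n_draws = 100, n_sim = 1000,
                            seed = 1, strict = TRUE) {
  structure(list(out_dir = out_dir, inputs = inputs, beta = beta,
                 max_iter = max_iter, background_n = background_n,
                 train_fraction = train_fraction,
                 cv_max_points = cv_max_points, replicates = replicates,
                 n_permutations = n_permutations,
                 n_keep_variables = n_keep_variables, n_bins = n_bins,
                 n_draws = n_draws, n_sim = n_sim, seed = seed,
                 strict = strict),
            class = "pipeline_config")
}

#' Load pipeline inputs
#'
#' @param inputs as in \code{\link{pipeline_config}}.
#' @param out_dir directory used when inputs must be simulated.
#' @return list: \code{stack}, \code{tree}, \code{occurrences},
#'   \code{clades}, \code{source}.
#' @export
load_inputs <- function(inputs, out_dir = tempdir()) {
  if (inherits(inputs, "sim_config")) {
    ds <- make_dataset(inputs, file.path(out_dir, "inputs"))
    list(stack = ds$stack, tree = ds$tree, occurrences = ds$occurrences,
         clades = ds$clades, source = "simulated")
  } else {
    stack <- read_layer_stack(inputs$layers)
    tree <- read_newick(inputs$tree)
    occ <- read_occurrences(inputs$occurrences, stack$spec)
    clades <- if (!is.null(inputs$clades))
      read_clade_map(inputs$clades, tree)
    list(stack = stack, tree = tree, occurrences = occ, clades = clades,
         source = "files")
  }
}

#' Validate pipeline inputs
#'
#' Checks label agreement between tree, occurrences and clade table, the
#' 10-point minimum per species, and that occurrence cells are valid in
#' the climate stack.  Issues are reported, not thrown.
#'
#' @param data a \code{\link{load_inputs}} result.
#' @param min_points minimum spatially unique points per species.
#' @return data.frame with columns \code{check} and \code{detail}; zero
#'   rows when the inputs are clean.
#' @export
validate_inputs <- function(data, min_points = 10) {
  issues <- list()
  note <- function(check, detail)
    issues[[length(issues) + 1L]] <<- data.frame(check = check,
                                                 detail = detail)
  tips <- data$tree$tip.label
  occ_sp <- names(data$occurrences)
  for (sp in setdiff(tips, occ_sp))
    note("missing_occurrences", sp)
  for (sp in setdiff(occ_sp, tips))
    note("species_not_in_tree", sp)
  for (sp in intersect(tips, occ_sp)) {
    n <- length(data$occurrences[[sp]]$cells)
    if (n < min_points)
      note("too_few_points", sprintf("%s: %d < %d", sp, n, min_points))
    bad <- !data$stack$valid[data$occurrences[[sp]]$cells]
    if (any(bad))
      note("occurrence_on_invalid_cell",
           sprintf("%s: %d cell(s)", sp, sum(bad)))
  }
  if (!is.null(data$clades)) {
    cl_ok <- tryCatch({ clade_map(data$clades, data$tree); TRUE },
                      error = function(e) { note("clade_map", conditionMessage(e)); FALSE })
    invisible(cl_ok)
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(check = character(0), detail = character(0))
}

## one ENM pass over all species against a given stack
run_enm_stage <- function(data, stack, cfg) {
  all_pts <- do.call(rbind, lapply(data$occurrences, function(o) o$points))
  poly <- minimum_convex_polygon(all_pts)
  bg <- build_background(poly, stack, cfg$background_n,
                         seed = derive_seed(cfg$seed, "background"))
  feats <- build_features(stack, bg)
  fits <- lapply(data$occurrences, function(occ)
    fit_species_enm(occ, bg, feats, beta = cfg$beta,
                    max_iter = cfg$max_iter,
                    train_fraction = cfg$train_fraction,
                    cv_max_points = cfg$cv_max_points,
                    replicates = cfg$replicates,
                    n_permutations = cfg$n_permutations,
                    seed = derive_seed(cfg$seed, paste0("enm:", occ$species))))
  list(fits = fits, background = bg, features = feats, polygon = poly)
}

enm_report_df <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    r <- f$report
    cbind(data.frame(species = r$species, n_points = r$n_points,
                     auc = r$auc, method = r$method,
                     replicates = r$replicates),
          as.data.frame(as.list(round(r$contributions, 3))))
  }))
}

#' Run the full phyloclimatic pipeline
#'
#' Stages: (1) simulate or load inputs; (2) validate; (3) per-species
#' niche models on all layers, with AUC and variable contributions;
#' (4) retain the top contributing variables and refit if fewer than the
#' layer count; (5) pairwise overlap matrix (D/I); (6) PNO profiles;
#' (7) ancestral reconstruction per variable; (8) DTT + MDI, whole-tree
#' and per clade.  All outputs land under \code{config$out_dir}; a
#' manifest JSON records seeds and MD5 hashes of every written file, and a
#' rerun with the same config is byte-identical.
#'
#' @param config a \code{\link{pipeline_config}} (or a YAML file path
#'   holding its fields).
#' @return invisibly, a list with the stage results (\code{report},
#'   \code{overlap}, \code{pno}, \code{history}, \code{dtt},
#'   \code{manifest}, \code{kept_variables}, ...).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    y <- yaml::read_yaml(config)
    inputs <- if (!is.null(y$inputs$simulate))
      do.call(sim_config, y$inputs$simulate) else y$inputs
    y$inputs <- inputs
    config <- do.call(pipeline_config, y)
  }
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf(
    "[%7.1fs] stage %s (seed %d)", proc.time()[["elapsed"]] - t0, name,
    derive_seed(config$seed, name)))
  written <- character(0)
  keep <- function(path) { written <<- c(written, path); path }

  stage("inputs")
  data <- load_inputs(config$inputs, out)

  stage("validate")
  issues <- validate_inputs(data)
  utils::write.csv(issues, keep(file.path(out, "validation.csv")),
                   row.names = FALSE)
  if (nrow(issues) > 0 && config$strict)
    abort("input validation failed (", nrow(issues), " issue(s); see ",
          file.path(out, "validation.csv"), ")")

  stage("enm")
  enm <- run_enm_stage(data, data$stack, config)
  all_vars <- names(data$stack$layers)
  kept <- if (config$n_keep_variables < length(all_vars)) {
    select_top_variables(lapply(enm$fits, `[[`, "report"),
                         config$n_keep_variables)
  } else all_vars
  if (length(kept) < length(all_vars)) {
    stage("enm-refit")
    sub_stack <- raster_stack(data$stack$layers[sort(kept)])
    enm <- run_enm_stage(data, sub_stack, config)
  } else sub_stack <- data$stack
  report <- enm_report_df(enm$fits)
  utils::write.csv(report, keep(file.path(out, "enm_report.csv")),
                   row.names = FALSE)
  surf_dir <- file.path(out, "surfaces")
  dir.create(surf_dir, showWarnings = FALSE)
  surfaces <- lapply(enm$fits, `[[`, "surface")
  for (sp in names(surfaces))
    write_ascii_grid(surfaces[[sp]],
                     keep(file.path(surf_dir, paste0(sp, ".asc"))))

  stage("overlap")
  om <- overlap_matrix(surfaces, clades = data$clades)
  write_overlap_csv(om, keep(file.path(out, "overlap.csv")))

  stage("pno")
  profiles <- lapply(sort(kept), function(v) {
    lapply(surfaces, compute_pno,
           variable_raster = sub_stack$layers[[v]],
           n_bins = config$n_bins)
  })
  names(profiles) <- sort(kept)
  for (v in names(profiles))
    write_pno_csv(profiles[[v]],
                  keep(file.path(out, paste0("pno_", v, ".csv"))))

  stage("reconstruct")
  history <- lapply(names(profiles), function(v)
    reconstruct_history(data$tree, profiles[[v]], n_draws = config$n_draws,
                        seed = derive_seed(config$seed, paste0("rec:", v))))
  names(history) <- names(profiles)
  for (v in names(history))
    utils::write.csv(history[[v]]$summary,
                     keep(file.path(out, paste0("nodes_", v, ".csv"))),
                     row.names = FALSE)

  stage("dtt")
  dtt <- dtt_pipeline(data$tree, profiles, clades = data$clades,
                      n_sim = config$n_sim,
                      seed = derive_seed(config$seed, "dtt"))
  utils::write.csv(dtt$table, keep(file.path(out, "mdi.csv")),
                   row.names = FALSE)
  for (v in names(dtt$curves))
    write_dtt_csv(dtt$curves[[v]]$observed, dtt$curves[[v]]$null,
                  keep(file.path(out, paste0("dtt_", v, ".csv"))))

  manifest <- list(
    package = "phyloenm",
    version = as.character(utils::packageVersion("phyloenm")),
    seed = config$seed,
    stages = c("inputs", "validate", "enm", "overlap", "pno",
               "reconstruct", "dtt"),
    kept_variables = sort(kept),
    files = {   # keyed by path relative to out_dir, so reruns compare equal
      fm <- tools::md5sum(sort(written))
      names(fm) <- substring(names(fm), nchar(out) + 2)
      as.list(fm)
    })
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("[%7.1fs] pipeline complete: %s",
                  proc.time()[["elapsed"]] - t0, out))
  invisible(list(config = config, data = data, report = report,
                 surfaces = surfaces, overlap = om, pno = profiles,
                 history = history, dtt = dtt, kept_variables = sort(kept),
                 manifest = manifest))
}
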