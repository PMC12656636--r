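#' End-to-end run configuration
#'
#' Bundles every stage's settings with one global seed; all stage seeds are
#' derived deterministically from it, so a config + seed pair fully
#' determines the run. Defaults describe the desk-scale synthetic study:
#' 256 x 256 island at 20 m, fit scale 60 m, consolidation at 30 m,
#' cluster-holdout at 250 m, 300 m accessible mask with a 25:1 background
#' target, Spec0.980 + Q90 coastal belt + MMU 3 decision layer, and
#' mask/ratio and belt/MMU sweeps.
#'
#' @param island list of [island_config()] overrides.
#' @param truth list of [truth_params()] overrides.
#' @param terrain list of [terrain_config()] overrides.
#' @param n_sites simulated site count.
#' @param consolidation_eps_m site consolidation radius (m).
#' @param loco_eps_m cluster-holdout radius (m).
#' @param train_periods periods whose presences train the model.
#' @param select_grid `NULL` to fit `fixed_config` directly, or a list with
#'   `classes` and `rm` vectors for the selection grid.
#' @param fixed_config list of [model_config()] overrides used when
#'   `select_grid` is `NULL` (and as the template config otherwise).
#' @param protected_vars variables protected from collinearity pruning.
#' @param belt_q quantile for the coastal-belt width.
#' @param mmu_cells minimum mapping unit (cells).
#' @param sweep_masks_m,sweep_ratios mask/ratio sweep settings.
#' @param sweep_belts_m,sweep_mmus belt/MMU sweep settings.
#' @param segment_len_m coastline segment length (m).
#' @param seed global seed.
#' @param public_mode suppress coordinate-bearing exports.
#' @return list of class `run_config`.
#' @export
run_config <- function(island = list(), truth = list(), terrain = list(fit_cell_m = 60),
                       n_sites = 45, consolidation_eps_m = 30,
                       loco_eps_m = 250, train_periods = c("P3", "P4"),
                       select_grid = NULL,
                       fixed_config = list(feature_classes = "lq", rm = 1.4),
                       protected_vars = c("DIST_COAST_M", "ELEV_M",
                                          "TWI_APPROX"),
                       belt_q = 0.90, mmu_cells = 3,
                       sweep_masks_m = c(300, 450, 600),
                       sweep_ratios = c(10, 15, 20, 25, 30),
                       sweep_belts_m = c(60, 90, 120),
                       sweep_mmus = c(1, 3, 5, 9),
                       segment_len_m = 100, seed = 42, public_mode = FALSE) {
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

log_stage <- function(stage, t0, ...) {
  extras <- paste(c(...), collapse = " ")
  message(sprintf("[%s] %.1fs %s", stage,
                  as.numeric(Sys.time()) - t0, extras))
}

#' Run the full blueprint
#'
#' Simulate island and surveys, derive predictors, prune, select/fit the
#' model, validate with cluster holdout, build the decision products, run
#' the sensitivity sweeps, rank survey segments, and write every output with
#' a hash manifest. With `public_mode` no coordinate-bearing file is
#' written.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return list of class `blueprint_run` with all intermediate objects and
#'   the manifest.
#' @export
run_blueprint <- function(config = run_config(), out_dir = tempfile("ccrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(Sys.time())
  seed <- config$seed

  icfg <- do.call(island_config,
                  utils::modifyList(config$island,
                                    list(seed = stage_seed(seed, "island"))))
  dem <- generate_dem(icfg)
  log_stage("island", t0, sprintf("%d land cells", sum(!is.na(dem$v))))

  tcfg <- do.call(terrain_config, config$terrain)
  stack_map <- build_predictors(dem, tcfg)
  st <- scale_transfer(stack_map, tcfg$fit_cell_m)
  log_stage("terrain", t0, sprintf("fit scale %g m", tcfg$fit_cell_m))

  tpar <- do.call(truth_params, config$truth)
  truth <- truth_suitability(stack_map, tpar)
  surveys <- simulate_surveys(truth, n_sites = config$n_sites,
                              seed = stage_seed(seed, "surveys"),
                              jitter_sd_m = tpar$jitter_sd_m)
  occ <- assign_periods(surveys) |>
    consolidate_sites(eps_m = config$consolidation_eps_m)
  log_stage("surveys", t0, sprintf("%d records, %d sites",
                                   nrow(occ), length(unique(occ$site_cluster))))

  per_period <- occ |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      n_sites = length(unique(.data$site_cluster)),
      n_presence_sites = length(unique(.data$site_cluster[.data$presence])),
      .groups = "drop") |>
    dplyr::filter(.data$period != "none")
  rates <- dplyr::bind_rows(lapply(seq_len(nrow(per_period)), function(i) {
    dplyr::mutate(detection_rate_ci(per_period$n_presence_sites[i],
                                    per_period$n_sites[i],
                                    seed = stage_seed(seed, "boot")),
                  period = per_period$period[i])
  }))
  change <- grid_change_classify(occ, cell_m = 500)
  deid <- deidentify_export(occ, cell_m = 500)
  log_stage("dynamics", t0)

  # training presences: unique sites with a recent-window presence
  pres_sites <- occ |>
    dplyr::filter(.data$presence, .data$period %in% config$train_periods) |>
    site_representatives()
  fit_tbl <- as_tibble.pred_stack(st$fit)
  pcell <- cr_cell_at(st$fit$layers[[1]], pres_sites$x, pres_sites$y)
  pres_idx <- match(paste(pcell$row, pcell$col),
                    paste(fit_tbl$row, fit_tbl$col))
  ok <- !is.na(pres_idx)
  pres_sites <- pres_sites[ok, ]; pcell <- pcell[ok, ]
  pres_rows_all <- fit_tbl[pres_idx[ok], ]

  mcfg0 <- do.call(model_config, config$fixed_config)
  mask_fit <- accessible_mask(st$fit, mcfg0$mask_dist_m)
  bg <- sample_background(mask_fit, nrow(pres_sites),
                          mcfg0$background_target_ratio,
                          seed = stage_seed(seed, "background"))
  bg_rows_all <- fit_tbl[match(paste(bg$row, bg$col),
                               paste(fit_tbl$row, fit_tbl$col)), ]

  all_vars <- names(stack_map$layers)
  kept <- spearman_prune(bg_rows_all[all_vars], 0.7, config$protected_vars)
  kept <- vif_prune(bg_rows_all[kept], 5, intersect(config$protected_vars, kept))
  pres_df <- pres_rows_all[kept]; bg_df <- bg_rows_all[kept]
  log_stage("prune", t0, paste(kept, collapse = ","))

  if (!is.null(config$select_grid)) {
    sel <- select_model_grid(pres_df, bg_df,
                             classes_grid = config$select_grid$classes,
                             rm_grid = config$select_grid$rm,
                             seed = stage_seed(seed, "select"),
                             hinge_knots = mcfg0$hinge_knots)
    mcfg <- model_config(sel$best$classes, rm = sel$best$rm,
                         hinge_knots = mcfg0$hinge_knots,
                         background_target_ratio = mcfg0$background_target_ratio,
                         mask_dist_m = mcfg0$mask_dist_m, seed = mcfg0$seed)
    fit <- sel$best_fit
  } else {
    sel <- NULL
    mcfg <- mcfg0
    fit <- fit_maxent(pres_df, bg_df, mcfg)
  }
  log_stage("fit", t0, sprintf("classes %s rm %g k %d",
                               paste(mcfg$feature_classes, collapse = ""),
                               mcfg$rm, fit$k))

  # step down the supported sensitivity radii if everything chains into one
  # cluster at the configured radius
  eps_used <- config$loco_eps_m
  folds <- NULL
  for (eps_try in unique(c(eps_used, 200, 150, 100, 80, 50))) {
    f <- tryCatch(loco_folds(pres_sites, eps_m = eps_try)$fold,
                  error = function(e) NULL)
    if (!is.null(f)) { folds <- f; eps_used <- eps_try; break }
  }
  if (is.null(folds)) stop("presences form a single cluster at every supported eps")
  if (eps_used != config$loco_eps_m) {
    warning(sprintf("single presence cluster at eps %g m; holdout uses %g m",
                    config$loco_eps_m, eps_used))
  }
  report <- evaluate_loco(pres_df, bg_df, folds, mcfg,
                          bg_cells = bg[, c("row", "col")],
                          presence_cells = pcell)
  report$eps_m <- eps_used
  log_stage("loco", t0, sprintf("AUC %.3f",
                                report$summary$mean[report$summary$metric == "auc"]))

  suit <- predict_map(fit, stack_map)
  pres_pred <- predict(fit, pres_df, type = "cloglog")
  bg_pred <- predict(fit, bg_df, type = "cloglog")
  fold_youden <- vapply(sort(unique(folds)), function(f) {
    youden_threshold(pres_pred[folds == f], bg_pred)
  }, 0)
  pres_dists <- stack_map$layers$DIST_COAST_M$v[
    as.matrix(cr_cell_at(stack_map$layers$DIST_COAST_M,
                         pres_sites$x, pres_sites$y))]
  pres_dists <- pres_dists[!is.na(pres_dists)]
  belt <- coastal_belt(pres_dists, stack_map$layers$DIST_COAST_M,
                       q = config$belt_q)
  thresholds <- dplyr::bind_rows(
    compute_threshold("spec0980", background_preds = bg_pred),
    compute_threshold("tp10", presence_preds = pres_pred),
    compute_threshold("balanced_apparent", pres_pred, bg_pred),
    compute_threshold("maxtss", pres_pred, bg_pred),
    compute_threshold("max_ba", pres_pred, bg_pred),
    compute_threshold("coverage_target", pres_pred, bg_pred,
                      belt_presence_preds = pres_pred[
                        pres_dists <= belt$width_m]),
    compute_threshold("balanced_cv", fold_thresholds = fold_youden))
  theta <- thresholds$theta[thresholds$rule == "spec0980"]
  core <- suppressWarnings(
    core_map(suit, theta, belt, config$mmu_cells, pres_sites))
  log_stage("decide", t0, sprintf("theta %.3f core %.4f km2 coverage %s",
                                  theta, core$area_km2,
                                  format(core$coverage, digits = 3)))

  sweep <- mask_ratio_sweep(st$fit, stack_map, pres_df, pres_sites, belt,
                            mcfg, config$sweep_masks_m, config$sweep_ratios,
                            config$mmu_cells, vars = kept,
                            seed = stage_seed(seed, "sweep"))
  theta_named <- setNames(thresholds$theta, thresholds$rule)
  bsweep <- belt_mmu_sweep(suit, theta_named[c("spec0980", "maxtss", "max_ba")],
                           stack_map$layers$DIST_COAST_M,
                           config$sweep_belts_m, config$sweep_mmus,
                           pres_sites)
  shore <- shoreline_from_dem(dem)
  segments <- segment_rank(shore$rings, suit, theta, belt,
                           segment_len_m = config$segment_len_m)
  log_stage("sweep", t0, sprintf("band %.4f-%.4f km2",
                                 sweep$band$min, sweep$band$max))

  # ---- outputs -------------------------------------------------------------
  wpath <- function(f) file.path(out_dir, f)
  write_ascii_grid(suit, wpath("suitability_cloglog.asc"))
  write_ascii_grid(core$core, wpath("core.asc"))
  write_model_json(fit, wpath("model.json"))
  write.csv(tidy(report), wpath("validation_folds.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(label = report$label, eps_m = report$eps_m,
         summary = report$summary),
    wpath("validation_summary.json"), auto_unbox = TRUE, digits = NA)
  write.csv(thresholds, wpath("thresholds.csv"), row.names = FALSE)
  write.csv(sweep$runs, wpath("sweep_mask_ratio.csv"), row.names = FALSE)
  jsonlite::write_json(sweep$band, wpath("area_band.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(bsweep$grid, wpath("sweep_belt_mmu.csv"), row.names = FALSE)
  write.csv(deid, wpath("deidentified_grid.csv"), row.names = FALSE)
  write.csv(rates, wpath("detection_rates.csv"), row.names = FALSE)
  write.csv(change[c("cell_i", "cell_j", "class")],
            wpath("change_grid.csv"), row.names = FALSE)
  if (!config$public_mode) {
    write_ascii_grid(dem, wpath("dem.asc"))
    write.csv(occ, wpath("occurrences.csv"), row.names = FALSE)
    write.csv(pres_sites, wpath("presence_sites.csv"), row.names = FALSE)
    write_segments_geojson(segments, wpath("segments.geojson"))
  }
  files <- sort(list.files(out_dir, full.names = FALSE))
  manifest <- list(
    seed = seed, public_mode = config$public_mode,
    stage_seeds = list(island = stage_seed(seed, "island"),
                       surveys = stage_seed(seed, "surveys"),
                       background = stage_seed(seed, "background"),
                       select = stage_seed(seed, "select"),
                       sweep = stage_seed(seed, "sweep")),
    chosen = list(classes = paste(mcfg$feature_classes, collapse = ""),
                  rm = mcfg$rm, theta_spec0980 = theta,
                  belt_width_m = belt$width_m),
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, wpath("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done", t0, out_dir)

  structure(list(config = config, dem = dem, stack_map = stack_map,
                 stack_fit = st$fit, truth = truth, occurrences = occ,
                 detection_rates = rates, change_grid = change,
                 presence_sites = pres_sites, presence_df = pres_df,
                 background = bg, background_df = bg_df,
                 retained_vars = kept, selection = sel, fit = fit,
                 report = report, suitability = suit,
                 thresholds = thresholds, belt = belt, core = core,
                 sweep = sweep, belt_mmu = bsweep, segments = segments,
                 manifest = manifest, out_dir = out_dir),
            class = "blueprint_run")
}

#' @export
print.blueprint_run <- function(x, ...) {
  cat("<blueprint_run>\n")
  print(x$fit)
  print(x$report)
  print(x$core)
  invisible(x)
}
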