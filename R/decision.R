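#' Threshold menu for binarizing suitability
#'
#' Rules (all on the cloglog scale, inclusive at the threshold):
#' * `spec0980` -- 0.98 empirical quantile of background predictions
#'   (guarantees specificity of at least 0.98 on the training background);
#' * `tp10` -- 0.10 quantile of presence predictions;
#' * `balanced_apparent` / `maxtss` -- Youden-optimal (max sens + spec - 1)
#'   over unique scores, full-data;
#' * `max_ba` -- max balanced accuracy (same argmax set as Youden, reported
#'   separately);
#' * `coverage_target` -- smallest unique score keeping at least `0.90` of
#'   belt presences at or above it;
#' * `balanced_cv` -- median of per-fold Youden thresholds.
#' Quantiles use the linear-interpolation (type 7) convention. Youden-type
#' argmax ties resolve to the smallest maximizing score, reported as the
#' midpoint to the next unique score below (strictly between separated
#' classes).
#'
#' @param rule one of the rule names above.
#' @param presence_preds,background_preds cloglog predictions.
#' @param fold_thresholds per-fold Youden thresholds (for `balanced_cv`).
#' @param belt_presence_preds presence predictions inside the coastal belt
#'   (for `coverage_target`); defaults to `presence_preds`.
#' @param coverage target coverage for `coverage_target`.
#' @return tibble: `rule`, `theta`, `provenance`.
#' @export
compute_threshold <- function(rule, presence_preds = NULL,
                              background_preds = NULL,
                              fold_thresholds = NULL,
                              belt_presence_preds = NULL,
                              coverage = 0.90) {
  rule <- match.arg(rule, c("balanced_apparent", "balanced_cv", "tp10",
                            "coverage_target", "spec0980", "maxtss", "max_ba"))
  need <- function(x, what) {
    if (is.null(x) || length(x) == 0) stop(rule, " requires nonempty ", what)
  }
  theta <- switch(rule,
    spec0980 = {
      need(background_preds, "background predictions")
      th <- unname(quantile(background_preds, 0.98, type = 7))
      # the interpolated quantile can leave specificity a hair under 0.98
      # (by < 1/n); step up to the next unique score so the guarantee that
      # defines this rule holds exactly
      if (mean(background_preds < th) < 0.98) {
        u <- sort(unique(background_preds))
        ok <- u[vapply(u, function(s) mean(background_preds < s) >= 0.98, TRUE)]
        if (length(ok)) th <- min(ok)
      }
      th
    },
    tp10 = {
      need(presence_preds, "presence predictions")
      unname(quantile(presence_preds, 0.10, type = 7))
    },
    balanced_apparent = ,
    maxtss = ,
    max_ba = {
      need(presence_preds, "presence predictions")
      need(background_preds, "background predictions")
      youden_threshold(presence_preds, background_preds)
    },
    coverage_target = {
      bp <- belt_presence_preds %||% presence_preds
      need(bp, "belt presence predictions")
      th <- sort(unique(bp), decreasing = TRUE)
      ok <- th[vapply(th, function(t) mean(bp >= t) >= coverage, TRUE)]
      if (length(ok) == 0) stop("no threshold achieves the coverage target")
      min(ok)
    },
    balanced_cv = {
      need(fold_thresholds, "fold thresholds")
      median(fold_thresholds)
    })
  tibble::tibble(rule = rule, theta = theta,
                 provenance = switch(rule,
                   spec0980 = "training background quantile",
                   tp10 = "presence quantile",
                   coverage_target = "belt presence coverage",
                   balanced_cv = "median of fold Youden thresholds",
                   "full-data Youden"))
}

#' @rdname compute_threshold
#' @export
youden_threshold <- function(presence_preds, background_preds) {
  th <- sort(unique(c(presence_preds, background_preds)))
  j <- vapply(th, function(t) {
    mean(presence_preds >= t) + mean(background_preds < t) - 1
  }, 0)
  best <- th[j == max(j)]
  t_star <- min(best)
  below <- th[th < t_star]
  if (length(below)) (t_star + max(below)) / 2 else t_star
}

#' Binarize a suitability raster
#'
#' Cell = 1 iff score >= theta (inclusive), NA off-land.
#' @param suitability cloglog `crast`.
#' @param theta threshold in `[0, 1]`.
#' @export
binarize <- function(suitability, theta) {
  stopifnot(is_crast(suitability), theta >= 0)
  v <- ifelse(suitability$v >= theta, 1, 0)
  v[is.na(suitability$v)] <- NA
  crast(v, suitability$cell_m, suitability$xmin, suitability$ymin)
}

#' Coastal belt from recent presence coastal distances
#'
#' Belt width is the empirical `q` quantile (type 7) of recent presences'
#' distance to coast (the Q90 convention, about 90 m); the belt mask keeps
#' cells with `DIST_COAST_M <=` width. Explicit widths (e.g. 60/90/120 m)
#' override the quantile.
#'
#' @param recent_presence_dists coastal distances (m) of recent presences.
#' @param dist_coast_r `DIST_COAST_M` `crast`.
#' @param q quantile for the width.
#' @param width_m optional explicit width (m), bypassing the quantile.
#' @return list: `mask` (`crast`, 1 inside belt), `width_m`.
#' @export
coastal_belt <- function(recent_presence_dists = NULL, dist_coast_r, q = 0.90,
                         width_m = NULL) {
  if (is.null(width_m)) {
    if (is.null(recent_presence_dists) || length(recent_presence_dists) < 5) {
      stop("need at least 5 recent presences; supply width_m explicitly")
    }
    width_m <- unname(quantile(recent_presence_dists, q, type = 7))
  }
  v <- ifelse(dist_coast_r$v <= width_m, 1, 0)
  v[is.na(dist_coast_r$v)] <- NA
  list(mask = crast(v, dist_coast_r$cell_m, dist_coast_r$xmin, dist_coast_r$ymin),
       width_m = width_m)
}

#' Minimum-mapping-unit filter
#'
#' Removes connected components (8-neighbour by default) smaller than
#' `min_cells` from a 0/1 raster.
#'
#' @param binary 0/1 `crast`.
#' @param min_cells smallest retained patch size (cells).
#' @param connectivity 4 or 8.
#' @export
mmu_filter <- function(binary, min_cells = 3, connectivity = 8) {
  stopifnot(is_crast(binary), min_cells >= 1)
  mask <- !is.na(binary$v) & binary$v == 1
  lab <- cc_label(mask, connectivity)
  if (any(mask)) {
    sizes <- table(lab[!is.na(lab)])
    small <- as.integer(names(sizes)[sizes < min_cells])
    v <- binary$v
    v[!is.na(lab) & lab %in% small] <- 0
  } else {
    v <- binary$v
  }
  crast(v, binary$cell_m, binary$xmin, binary$ymin)
}

#' Off-belt leakage area
#'
#' Area (km^2) with predictions at or above `theta` outside the coastal
#' belt.
#' @param suitability cloglog `crast`.
#' @param theta threshold.
#' @param belt_mask belt `crast` (1 inside).
#' @export
leakage_area <- function(suitability, theta, belt_mask) {
  cr_check_same_geom(suitability, belt_mask)
  hot <- !is.na(suitability$v) & suitability$v >= theta
  outside <- is.na(belt_mask$v) | belt_mask$v != 1
  sum(hot & outside) * suitability$cell_m^2 / 1e6
}

#' CORE decision product
#'
#' CORE = MMU-filtered intersection of the thresholded suitability map and
#' the coastal belt. Reports area (cell count x cell area), coverage
#' (fraction of recent presence sites whose cell is CORE), pre-belt leakage,
#' and post-belt leakage (zero by construction, asserted).
#'
#' @param suitability cloglog `crast`.
#' @param theta threshold.
#' @param belt output of [coastal_belt()].
#' @param min_cells MMU patch size.
#' @param recent_sites tibble of recent presence sites (`x`, `y`).
#' @return list of class `core_product`.
#' @export
core_map <- function(suitability, theta, belt, min_cells = 3,
                     recent_sites = NULL) {
  bin <- binarize(suitability, theta)
  inbelt <- bin
  inbelt$v <- ifelse(!is.na(bin$v) & bin$v == 1 &
                       !is.na(belt$mask$v) & belt$mask$v == 1, 1, 0)
  inbelt$v[is.na(bin$v)] <- NA
  core <- mmu_filter(inbelt, min_cells = min_cells, connectivity = 8)
  area_km2 <- cr_area(core)
  if (area_km2 == 0) warning("CORE is empty at these settings")
  coverage <- NA_real_
  if (!is.null(recent_sites) && nrow(recent_sites) > 0) {
    cells <- cr_cell_at(core, recent_sites$x, recent_sites$y)
    inside <- !is.na(cells$row) &
      !is.na(core$v[cbind(cells$row, cells$col)]) &
      core$v[cbind(cells$row, cells$col)] == 1
    coverage <- mean(inside)
  }
  leak_pre <- leakage_area(suitability, theta, belt$mask)
  leak_post <- leakage_area_core(core, belt$mask)
  stopifnot(leak_post == 0)
  structure(list(theta = theta, belt_width_m = belt$width_m,
                 min_cells = min_cells, core = core, area_km2 = area_km2,
                 coverage = coverage, leakage_pre_km2 = leak_pre,
                 leakage_post_km2 = leak_post),
            class = "core_product")
}

# area of core cells outside the belt (post-processing leakage)
leakage_area_core <- function(core, belt_mask) {
  hot <- !is.na(core$v) & core$v == 1
  outside <- is.na(belt_mask$v) | belt_mask$v != 1
  sum(hot & outside) * core$cell_m^2 / 1e6
}

#' @export
print.core_product <- function(x, ...) {
  cat(sprintf(
    "<core_product> theta = %.3f, belt %.0f m, MMU %d cells\n  area %.4f km^2, coverage %s, leakage pre-belt %.4f km^2 (post-belt %.4f)\n",
    x$theta, x$belt_width_m, x$min_cells, x$area_km2,
    ifelse(is.na(x$coverage), "NA", sprintf("%.1f%%", 100 * x$coverage)),
    x$leakage_pre_km2, x$leakage_post_km2))
  invisible(x)
}

#' @method glance core_product
#' @export
glance.core_product <- function(x, ...) {
  tibble::tibble(theta = x$theta, belt_width_m = x$belt_width_m,
                 min_cells = x$min_cells, area_km2 = x$area_km2,
                 coverage = x$coverage, leakage_pre_km2 = x$leakage_pre_km2,
                 leakage_post_km2 = x$leakage_post_km2)
}

#' Min-max area band across sensitivity runs
#'
#' @param areas_km2 vector of post-processed CORE areas.
#' @return tibble: `min`, `max`, `spread` (max - min) and
#'   `percent_increase` (100 * spread / min).
#' @export
area_band <- function(areas_km2) {
  areas_km2 <- areas_km2[is.finite(areas_km2)]
  stopifnot(length(areas_km2) >= 1)
  lo <- min(areas_km2); hi <- max(areas_km2)
  tibble::tibble(min = lo, max = hi, spread = hi - lo,
                 percent_increase = round(100 * (hi - lo) / lo, 1))
}

#' Accessible-mask x background-ratio sensitivity sweep
#'
#' For every mask width x ratio combination: resample the background, refit
#' the chosen model, recompute the Spec0.980 threshold from that run's own
#' training background predictions, post-process (belt + MMU), and record
#' area and coverage. The area band summarises the post-processed CORE
#' spread.
#'
#' @param stack_fit fitting-scale `pred_stack`.
#' @param stack_map mapping-scale `pred_stack`.
#' @param presence_df presence predictor rows (fitting scale).
#' @param presence_sites tibble of presence sites (`x`, `y`) for coverage.
#' @param belt output of [coastal_belt()] on the mapping scale.
#' @param config a [model_config()]; its classes/RM are refit per run.
#' @param masks_m accessible-mask widths (m).
#' @param ratios background:presence ratios.
#' @param min_cells MMU size.
#' @param vars variables used by the model.
#' @param seed integer; per-run seeds derive deterministically from it.
#' @return list of class `sweep_result`: `runs` tibble and `band`.
#' @export
mask_ratio_sweep <- function(stack_fit, stack_map, presence_df,
                             presence_sites, belt, config = model_config(),
                             masks_m = c(300, 450, 600),
                             ratios = c(10, 15, 20, 25, 30),
                             min_cells = 3, vars = NULL, seed = 42) {
  stopifnot(length(masks_m) >= 1, length(ratios) >= 1)
  vars <- vars %||% names(presence_df)
  fit_tbl <- as_tibble.pred_stack(stack_fit)
  rows <- list()
  for (mk in masks_m) {
    mask <- accessible_mask(stack_fit, mk)
    for (rt in ratios) {
      run_seed <- stage_seed(seed, sprintf("sweep-%d-%d", mk, rt))
      res <- tryCatch({
        bg <- sample_background(mask, nrow(presence_df), rt, seed = run_seed)
        bg_df <- fit_tbl[match(paste(bg$row, bg$col),
                               paste(fit_tbl$row, fit_tbl$col)), vars]
        fit <- fit_maxent(presence_df[vars], bg_df, config)
        theta <- compute_threshold(
          "spec0980",
          background_preds = predict(fit, bg_df, type = "cloglog"))$theta
        suit <- predict_map(fit, stack_map)
        prod <- suppressWarnings(
          core_map(suit, theta, belt, min_cells, presence_sites))
        tibble::tibble(mask_m = mk, ratio = rt, theta = theta,
                       realized_ratio = attr(bg, "realized_ratio"),
                       core_area_km2 = prod$area_km2,
                       coverage = prod$coverage, failed = FALSE)
      }, error = function(e) {
        warning(sprintf("sweep run mask %d ratio %d failed: %s",
                        mk, rt, conditionMessage(e)))
        tibble::tibble(mask_m = mk, ratio = rt, theta = NA_real_,
                       realized_ratio = NA_real_, core_area_km2 = NA_real_,
                       coverage = NA_real_, failed = TRUE)
      })
      rows[[length(rows) + 1]] <- res
    }
  }
  runs <- dplyr::bind_rows(rows)
  structure(list(runs = runs,
                 band = area_band(runs$core_area_km2[!runs$failed]),
                 seed = seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d runs (%d failed)\n",
              nrow(x$runs), sum(x$runs$failed)))
  print(x$band)
  invisible(x)
}

#' @method tidy sweep_result
#' @export
tidy.sweep_result <- function(x, ...) x$runs

#' @method glance sweep_result
#' @export
glance.sweep_result <- function(x, ...) x$band

#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$ratio, y = .data$core_area_km2,
                               colour = factor(.data$mask_m))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "background : presence ratio",
                  y = expression("post-processed CORE area" ~ (km^2)),
                  colour = "mask (m)")
}

#' Coastal-belt x MMU robustness sweep
#'
#' Recomputes CORE area and pre-belt leakage for every threshold rule x belt
#' width x MMU combination, and reports whether area is monotone
#' nonincreasing in MMU at fixed belt.
#'
#' @param suitability cloglog `crast` (mapping scale).
#' @param theta_rules named numeric vector of thresholds.
#' @param dist_coast_r `DIST_COAST_M` `crast` (mapping scale).
#' @param belts_m belt widths (m).
#' @param mmus MMU sizes (cells).
#' @param recent_sites sites for coverage (optional).
#' @return list: `grid` tibble, `monotone_mmu` flag.
#' @export
belt_mmu_sweep <- function(suitability, theta_rules, dist_coast_r,
                           belts_m = c(60, 90, 120), mmus = c(1, 3, 5, 9),
                           recent_sites = NULL) {
  rows <- list()
  for (rn in names(theta_rules)) {
    for (b in belts_m) {
      belt <- coastal_belt(dist_coast_r = dist_coast_r, width_m = b)
      for (mm in mmus) {
        prod <- suppressWarnings(core_map(suitability, theta_rules[[rn]],
                                          belt, mm, recent_sites))
        rows[[length(rows) + 1]] <- tibble::tibble(
          rule = rn, belt_m = b, mmu = mm, theta = theta_rules[[rn]],
          area_km2 = prod$area_km2, coverage = prod$coverage,
          leakage_pre_km2 = prod$leakage_pre_km2,
          leakage_post_km2 = prod$leakage_post_km2)
      }
    }
  }
  grid <- dplyr::bind_rows(rows)
  mono <- grid |>
    dplyr::arrange(.data$rule, .data$belt_m, .data$mmu) |>
    dplyr::group_by(.data$rule, .data$belt_m) |>
    dplyr::summarise(ok = all(diff(.data$area_km2) <= 1e-12), .groups = "drop")
  list(grid = grid, monotone_mmu = all(mono$ok))
}

#' Rank coastline segments for targeted surveys
#'
#' The shoreline ring is split into consecutive segments (default 100 m
#' alongshore); each segment takes the rolling median (window in segments)
#' of the cloglog value at the belt cell nearest its midpoint. Segments at
#' or above `theta` are candidates, ordered by score times optional
#' effort-gap and safety priors in `[0, 1]` (alongshore index breaks ties),
#' and reported as quantile priority bands -- never as absolute discovery
#' probabilities.
#'
#' @param rings shoreline rings tibble from [shoreline_from_dem()].
#' @param suitability cloglog `crast`.
#' @param theta candidate threshold.
#' @param belt output of [coastal_belt()].
#' @param segment_len_m segment length (m).
#' @param window_segments rolling-median window (odd).
#' @param effort,safety optional per-segment priors in `[0, 1]` (recycled).
#' @return tibble of candidate segments with `score`, `rank`, `band`,
#'   midpoint coordinates.
#' @export
segment_rank <- function(rings, suitability, theta, belt,
                         segment_len_m = 100, window_segments = 3,
                         effort = 1, safety = 1) {
  ring <- rings[rings$ring == 1, ]
  if (nrow(ring) < 2) stop("shoreline ring too short")
  dx <- diff(ring$x); dy <- diff(ring$y)
  seglen <- sqrt(dx^2 + dy^2)
  s <- c(0, cumsum(seglen))
  total <- max(s)
  if (total < 2 * segment_len_m) stop("shoreline shorter than two segments")
  n_seg <- floor(total / segment_len_m)
  mid_s <- (seq_len(n_seg) - 0.5) * segment_len_m
  mid_x <- approx(s, ring$x, xout = mid_s)$y
  mid_y <- approx(s, ring$y, xout = mid_s)$y
  # nearest belt cell-center to each midpoint
  bm <- belt$mask
  idx <- which(!is.na(bm$v) & bm$v == 1)
  bc <- cr_coords(bm, row(bm$v)[idx], col(bm$v)[idx])
  vals <- suitability$v[idx]
  score_raw <- vapply(seq_len(n_seg), function(i) {
    d2 <- (bc$x - mid_x[i])^2 + (bc$y - mid_y[i])^2
    vals[which.min(d2)]
  }, 0)
  med <- stats::runmed(score_raw, k = max(1, window_segments %/% 2 * 2 + 1),
                       endrule = "median")
  df <- tibble::tibble(segment = seq_len(n_seg), s_mid = mid_s,
                       x = mid_x, y = mid_y, score = as.numeric(med),
                       effort = rep_len(effort, n_seg),
                       safety = rep_len(safety, n_seg))
  cand <- df |>
    dplyr::filter(.data$score >= theta) |>
    dplyr::mutate(priority = .data$score * .data$effort * .data$safety) |>
    dplyr::arrange(dplyr::desc(.data$priority), .data$segment) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (nrow(cand) == 0) {
    message("no candidate segments at this threshold")
    return(dplyr::mutate(cand, band = character(0)))
  }
  qs <- (cand$rank - 1) / nrow(cand)
  dplyr::mutate(cand, band = dplyr::case_when(
    qs < 0.10 ~ "top 10%",
    qs < 0.25 ~ "10-25%",
    qs < 0.50 ~ "25-50%",
    TRUE ~ "bottom 50%"))
}

#' Export segments as GeoJSON points
#'
#' @param segments tibble from [segment_rank()].
#' @param path output path.
#' @export
write_segments_geojson <- function(segments, path) {
  feats <- lapply(seq_len(nrow(segments)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(segments$x[i], segments$y[i])),
         properties = list(segment = segments$segment[i],
                           score = segments$score[i],
                           rank = segments$rank[i],
                           band = segments$band[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
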