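#' Configuration for the synthetic volcanic island
#'
#' The generator emulates a small volcanic island: a radially decaying cone
#' with a central caldera depression, smoothed Gaussian roughness, and sea as
#' NoData. Defaults describe the desk-scale study landscape used throughout
#' the package's tests and examples: a 256 x 256 grid of 20 m cells, giving
#' an island about 4 km across (~13 km^2 with a ~16 km coastline and a 400 m
#' peak). At that size every absolute distance in the workflow -- 30 m site
#' consolidation, the ~90 m coastal belt, 250 m holdout clustering, the
#' 300 m accessible mask -- keeps a realistic proportion to the coastline,
#' while the grid stays small enough to analyse in seconds.
#'
#' @param grid_size cells per side (>= 64).
#' @param cell_m cell edge length, metres.
#' @param peak_elev_m maximum (rim) elevation, metres.
#' @param caldera_radius_frac caldera width as a fraction of island radius
#'   (0 disables the caldera).
#' @param caldera_depth_frac caldera depth as a fraction of `peak_elev_m`.
#' @param noise_sd_m sd of the Gaussian roughness field, metres.
#' @param ridge_amp relative amplitude of radial ridge-and-valley
#'   modulation of the cone (dissected volcanic flanks); 0 disables.
#' @param n_ridges number of radial ridges around the island.
#' @param island_radius_frac island radius as a fraction of the grid
#'   half-width.
#' @param seed integer; the same seed gives a bit-identical DEM.
#' @return a list of class `island_config`.
#' @export
island_config <- function(grid_size = 256, cell_m = 20, peak_elev_m = 400,
                          caldera_radius_frac = 0.3, caldera_depth_frac = 0.4,
                          noise_sd_m = 8, ridge_amp = 0.25, n_ridges = 6,
                          island_radius_frac = 0.8, seed = 42) {
  stopifnot(grid_size >= 64, cell_m > 0, peak_elev_m > 0,
            caldera_radius_frac >= 0, caldera_radius_frac < 1,
            caldera_depth_frac >= 0, caldera_depth_frac < 1,
            noise_sd_m >= 0, ridge_amp >= 0, ridge_amp < 1, n_ridges >= 1,
            island_radius_frac > 0, island_radius_frac <= 1)
  structure(as.list(environment()), class = "island_config")
}

#' Generate a synthetic island DEM
#'
#' Builds a cone `h(r) = peak * (1 - r/R)` with an inverted-Gaussian caldera
#' at the center, adds roughness (Gaussian noise smoothed by one pass of a
#' 3 x 3 mean filter), sets cells at or below sea level to NoData, and keeps
#' the largest connected landmass so the island is a single land body.
#'
#' @param config an [island_config()].
#' @return elevation `crast` (metres; sea = NA).
#' @export
generate_dem <- function(config = island_config()) {
  stopifnot(inherits(config, "island_config"))
  n <- config$grid_size
  half <- n * config$cell_m / 2
  R <- config$island_radius_frac * half
  xs <- (seq_len(n) - 0.5) * config$cell_m
  ys <- rev(xs)
  r <- sqrt(outer((ys - half)^2, rep(1, n)) +
            matrix((xs - half)^2, n, n, byrow = TRUE))
  h <- config$peak_elev_m * (1 - r / R)
  if (config$ridge_amp > 0) {
    # dissected flanks: radial ridge/valley modulation, tapered at the
    # summit so the rim stays coherent
    theta <- atan2(outer(ys - half, rep(1, n)),
                   matrix(xs - half, n, n, byrow = TRUE))
    taper <- pmin(r / R, 1)
    h <- h * (1 + config$ridge_amp * sin(config$n_ridges * theta) * taper)
  }
  if (config$caldera_radius_frac > 0) {
    sig <- config$caldera_radius_frac * R
    h <- h - config$caldera_depth_frac * config$peak_elev_m * exp(-(r / sig)^2)
  }
  if (config$noise_sd_m > 0) {
    noise <- withr::with_seed(config$seed,
                              matrix(rnorm(n * n, 0, config$noise_sd_m), n, n))
    h <- h + focal_disc(noise, 1.5, "mean")   # 3 x 3 mean smoothing
  }
  h[h <= 0] <- NA
  if (!any(!is.na(h))) stop("grid too small to contain an island at these parameters")
  lab <- cc_label(!is.na(h), connectivity = 4)
  h[is.na(lab) | lab != 1] <- NA
  # fill interior depressions disconnected from the open sea (lakes would
  # make the land/NoData shoreline ambiguous): label sea on a padded grid,
  # keep only the border-connected component as sea
  sea <- is.na(h)
  pad_sea <- matrix(TRUE, n + 2, n + 2)
  pad_sea[2:(n + 1), 2:(n + 1)] <- sea
  slab_pad <- cc_label(pad_sea, connectivity = 4)
  ocean <- slab_pad[1, 1]
  slab <- slab_pad[2:(n + 1), 2:(n + 1)]
  hole <- sea & !is.na(slab) & slab != ocean
  while (any(hole)) {
    hfill <- focal_disc(h, 1.5, "mean")
    fillable <- hole & !is.na(hfill)
    h[fillable] <- pmax(hfill[fillable], 0.1)
    hole <- hole & !fillable
  }
  h[!is.na(h)] <- pmin(h[!is.na(h)], config$peak_elev_m)
  crast(h, cell_m = config$cell_m)
}

#' Shoreline polygon and land mask from a DEM
#'
#' The shoreline is the polygonised land/NoData interface: every boundary
#' between a land cell and sea (or the grid edge) contributes a cell-edge
#' segment, and segments are chained into closed rings.
#'
#' @param dem elevation `crast` (sea = NA).
#' @return list with `land` (logical matrix), `rings` (tibble: `ring`, `seq`,
#'   `x`, `y` ordered vertices, closed), and `area_m2` (land area).
#' @export
shoreline_from_dem <- function(dem) {
  stopifnot(is_crast(dem))
  land <- !is.na(dem$v)
  if (!any(land)) stop("DEM has no land cells")
  nr <- nrow(land); nc <- ncol(land)
  cm <- dem$cell_m
  # corner (i, j): i in 0..nr from top, j in 0..nc from left
  vkey <- function(i, j) i * (nc + 1L) + j + 1L
  vx <- function(key) dem$xmin + ((key - 1L) %% (nc + 1L)) * cm
  vy <- function(key) dem$ymin + (nr - (key - 1L) %/% (nc + 1L)) * cm
  pad <- function(m, dr, dc) mat_shift(m, dr, dc, fill = FALSE)
  es <- list()
  idx <- which(land); rr <- row(land)[idx]; cc <- col(land)[idx]
  sea_above <- !pad(land, 1, 0)[idx]; sea_below <- !pad(land, -1, 0)[idx]
  sea_left  <- !pad(land, 0, 1)[idx]; sea_right <- !pad(land, 0, -1)[idx]
  es <- rbind(
    cbind(vkey(rr[sea_above] - 1L, cc[sea_above]),      vkey(rr[sea_above] - 1L, cc[sea_above] - 1L)),
    cbind(vkey(rr[sea_below], cc[sea_below] - 1L),      vkey(rr[sea_below], cc[sea_below])),
    cbind(vkey(rr[sea_left] - 1L, cc[sea_left] - 1L),   vkey(rr[sea_left], cc[sea_left] - 1L)),
    cbind(vkey(rr[sea_right], cc[sea_right]),           vkey(rr[sea_right] - 1L, cc[sea_right]))
  )
  # trace closed rings through the directed boundary edges
  used <- rep(FALSE, nrow(es))
  out_edges <- split(seq_len(nrow(es)), es[, 1])
  rings <- list(); ring_id <- 0L
  for (e0 in seq_len(nrow(es))) {
    if (used[e0]) next
    ring_id <- ring_id + 1L
    path <- integer(0)
    e <- e0
    repeat {
      used[e] <- TRUE
      path <- c(path, es[e, 1])
      nxt_candidates <- out_edges[[as.character(es[e, 2])]]
      nxt <- nxt_candidates[!used[nxt_candidates]]
      if (length(nxt) == 0) { path <- c(path, es[e, 2]); break }
      e <- nxt[1]
    }
    rings[[ring_id]] <- tibble::tibble(
      ring = ring_id, seq = seq_along(path),
      x = vx(path), y = vy(path))
  }
  # ring 1 = longest (the outer coastline)
  ord <- order(vapply(rings, nrow, 0L), decreasing = TRUE)
  rings <- lapply(seq_along(ord), function(i)
    dplyr::mutate(rings[[ord[i]]], ring = i))
  list(land = land, rings = dplyr::bind_rows(rings),
       area_m2 = sum(land) * cm^2)
}

#' Ground-truth suitability surface
#'
#' Logistic ground truth used for parameter-recovery experiments:
#' `plogis(intercept + beta_coast * DIST_COAST_M + beta_elev * ELEV_M +
#' beta_slope * SLOPE_DEG)`. The negative coastal-distance and elevation
#' defaults are the habitat signal the model is expected to recover; the
#' slope-avoidance term confines suitable habitat to flat near-shore
#' pockets (ledges, gravel benches) so that presences are both strongly
#' coastal and spatially clustered, as in real maritime-ecotone endemics --
#' without it, suitability would be a pure function of distance to coast
#' and the discrimination task would be artificially easy to saturate at a
#' low ceiling.
#'
#' @param beta_coast,beta_elev link-scale coefficients per metre (negative in
#'   the default scenario).
#' @param beta_slope link-scale coefficient per degree of patch-scale slope
#'   (negative: steep faces are avoided). The slope entering the truth is
#'   smoothed over `patch_radius_m` so that habitat pockets are larger
#'   than the GPS error -- plants occupy ledge and bench systems, not
#'   single 5 m cells.
#' @param beta_north link-scale coefficient on patch-scale northness
#'   (positive: the wind-exposed northern sectors carry the population
#'   core, the lee sectors only scattered satellites).
#' @param patch_radius_m smoothing radius (m) for the slope and northness
#'   terms.
#' @param beta_twi link-scale coefficient on the squared deviation of
#'   patch-scale wetness (`TWI_APPROX`) from `twi_opt` (negative: a
#'   unimodal preference for intermediate wetness). Together with the
#'   aspect preference this fragments the suitable belt into discrete
#'   pockets that the terrain predictors can explain.
#' @param twi_opt preferred wetness value on the `TWI_APPROX` scale.
#' @param patch_amp amplitude (link-scale sd) of a smooth, deterministic
#'   habitat-patchiness field (unmeasured microhabitat variation: substrate,
#'   crevices, disturbance history). Kept small by default: it adds realism
#'   as irreducible noise rather than structure.
#' @param patch_scale_m correlation length of the patchiness field (m).
#' @param patch_seed seed of the patchiness field (part of the landscape
#'   definition; the same parameters always give the same truth).
#' @param intercept link-scale offset.
#' @param jitter_sd_m GPS noise sd used by [simulate_surveys()].
#' @return a list of class `truth_params`.
#' @export
truth_params <- function(beta_coast = -0.10, beta_elev = -0.08,
                         beta_slope = -2, beta_north = 32,
                         beta_twi = -80, twi_opt = -1.0,
                         intercept = 3.8, patch_radius_m = 60,
                         patch_amp = 1, patch_scale_m = 400,
                         patch_seed = 7, jitter_sd_m = 10) {
  stopifnot(jitter_sd_m >= 0, patch_radius_m >= 0, patch_amp >= 0,
            patch_scale_m > 0)
  structure(as.list(environment()), class = "truth_params")
}

# smooth unit-variance random field: coarse white noise upsampled and
# lightly smoothed; deterministic in (seed, dims, scale)
patch_field <- function(nr, nc, cell_m, scale_m, seed) {
  f <- max(1L, as.integer(round(scale_m / (2 * cell_m))))
  nrc <- ceiling(nr / f) + 2; ncc <- ceiling(nc / f) + 2
  coarse <- withr::with_seed(seed, matrix(rnorm(nrc * ncc), nrc, ncc))
  up <- kronecker(coarse, matrix(1, f, f))[seq_len(nr) + f, seq_len(nc) + f]
  sm <- focal_disc(up, f, "mean")
  (sm - mean(sm)) / sd(sm)
}

#' @rdname truth_params
#' @param predictors a predictor stack containing `DIST_COAST_M`, `ELEV_M`
#'   and (when `beta_slope != 0`) `SLOPE_DEG` (see [build_predictors()]).
#' @param params a [truth_params()].
#' @export
truth_suitability <- function(predictors, params = truth_params()) {
  stopifnot(inherits(params, "truth_params"))
  need <- c("DIST_COAST_M", "ELEV_M")
  if (params$beta_slope != 0) need <- c(need, "SLOPE_DEG")
  if (params$beta_north != 0) need <- c(need, "NORTHNESS")
  if (params$beta_twi != 0) need <- c(need, "TWI_APPROX")
  miss <- setdiff(need, names(predictors$layers))
  if (length(miss)) stop("missing predictor layer(s): ", paste(miss, collapse = ", "))
  d <- predictors$layers$DIST_COAST_M; e <- predictors$layers$ELEV_M
  patch <- function(v) {
    if (params$patch_radius_m >= d$cell_m) {
      focal_disc(v, params$patch_radius_m / d$cell_m, "mean")
    } else v
  }
  link <- params$intercept + params$beta_coast * d$v + params$beta_elev * e$v
  if (params$beta_slope != 0) {
    link <- link + params$beta_slope * patch(predictors$layers$SLOPE_DEG$v)
  }
  if (params$beta_north != 0) {
    link <- link + params$beta_north * patch(predictors$layers$NORTHNESS$v)
  }
  if (params$beta_twi != 0) {
    tw <- patch(predictors$layers$TWI_APPROX$v)
    link <- link + params$beta_twi * (tw - params$twi_opt)^2
  }
  if (params$patch_amp > 0) {
    link <- link + params$patch_amp *
      patch_field(nrow(d$v), ncol(d$v), d$cell_m, params$patch_scale_m,
                  params$patch_seed)
  }
  p <- plogis(link)
  p[is.na(d$v) | is.na(e$v)] <- NA
  crast(p, d$cell_m, d$xmin, d$ymin)
}

#' Survey-period definitions
#'
#' Four national survey periods: P1 = 2008, P2 = 2014-2016, P3 = 2020-2022,
#' P4 = 2023-2024.
#' @export
default_periods <- function() {
  list(P1 = 2008, P2 = 2014:2016, P3 = 2020:2022, P4 = 2023:2024)
}

#' Simulate multi-period occurrence surveys on a truth surface
#'
#' Presence sites are drawn without replacement over land cells with
#' probability proportional to the truth suitability; each site is visited in
#' every period with imperfect detection, some sites are silently lost in the
#' final period, near-duplicate records 20-30 m from a site exercise the
#' consolidation step, and coordinates carry within-cell placement plus
#' Gaussian GPS jitter. Records with `count = 0` are non-detections.
#'
#' @param truth suitability `crast` from [truth_suitability()].
#' @param n_sites number of true sites (>= 1).
#' @param periods named list of period years; see [default_periods()].
#' @param seed integer seed (same seed, same table).
#' @param jitter_sd_m GPS jitter sd (m).
#' @param detect_p per-visit detection probability at an extant site;
#'   the default mirrors the stable 0.65-0.75 detection-rate band the
#'   workflow is designed to monitor.
#' @param dup_frac probability a detection also emits a near-duplicate record.
#' @param dup_dist_m range of duplicate offsets (m).
#' @param loss_frac fraction of sites absent in the last period.
#' @return tibble: `site_id`, `x`, `y`, `date`, `count`.
#' @export
simulate_surveys <- function(truth, n_sites = 30, periods = default_periods(),
                             seed = 1, jitter_sd_m = 10, detect_p = 0.7,
                             dup_frac = 0.3, dup_dist_m = c(20, 30),
                             loss_frac = 0.2) {
  stopifnot(is_crast(truth), n_sites >= 1, length(periods) >= 1)
  w <- truth$v
  ok <- which(!is.na(w) & w > 0)
  if (length(ok) == 0 || sum(w[ok]) <= 0) stop("truth surface is all zero")
  withr::with_seed(seed, {
    cells <- sample(ok, size = min(n_sites, length(ok)), prob = w[ok])
    co <- cr_coords(truth, row(w)[cells], col(w)[cells])
    half <- truth$cell_m / 2
    sx <- co$x + runif(length(cells), -half, half)
    sy <- co$y + runif(length(cells), -half, half)
    lost <- runif(length(cells)) < loss_frac
    last <- names(periods)[length(periods)]
    rows <- list()
    for (p in names(periods)) {
      yrs <- periods[[p]]
      for (i in seq_along(cells)) {
        yr <- if (length(yrs) == 1) yrs else sample(yrs, 1)
        date <- as.Date(sprintf("%d-%02d-%02d", yr, sample(4:10, 1), sample(1:28, 1)))
        extinct <- lost[i] && p == last
        det <- !extinct && runif(1) < detect_p
        cnt <- if (det) rpois(1, 3) + 1L else 0L
        jx <- if (jitter_sd_m > 0) rnorm(1, 0, jitter_sd_m) else 0
        jy <- if (jitter_sd_m > 0) rnorm(1, 0, jitter_sd_m) else 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          site_id = i, x = sx[i] + jx, y = sy[i] + jy, date = date, count = cnt)
        if (det && dup_frac > 0 && runif(1) < dup_frac) {
          ang <- runif(1, 0, 2 * pi)
          dd <- runif(1, dup_dist_m[1], dup_dist_m[2])
          rows[[length(rows) + 1]] <- tibble::tibble(
            site_id = i, x = sx[i] + dd * cos(ang), y = sy[i] + dd * sin(ang),
            date = date, count = max(1L, rpois(1, 2)))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
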