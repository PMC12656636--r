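#' Terrain derivation settings
#'
#' Parameters controlling the predictor derivation. Radii are metres;
#' `exposure_decay_m` is the e-folding length of the wave-exposure kernel
#' (plausible coastal-influence scales are 150-300 m); `cliff_slope_deg` is
#' the slope at or above which a cell counts as cliff; `fit_cell_m` and
#' `map_cell_m` define the fit-scale aggregation and native mapping scale.
#'
#' @param tpi_radius_m circular window radius for TPI.
#' @param relief_radius_m circular window radius for the wetness-proxy relief.
#' @param latitude_deg island latitude for the heat-load index.
#' @param exposure_decay_m wave-exposure decay length.
#' @param cliff_slope_deg cliff threshold, degrees (0, 90).
#' @param fit_cell_m model-fitting cell size; integer multiple of `map_cell_m`.
#' @param map_cell_m native mapping cell size.
#' @export
terrain_config <- function(tpi_radius_m = 90, relief_radius_m = 90,
                           latitude_deg = 37.5, exposure_decay_m = 200,
                           cliff_slope_deg = 40, fit_cell_m = 90,
                           map_cell_m = 5) {
  stopifnot(tpi_radius_m > 0, relief_radius_m > 0,
            latitude_deg > -90, latitude_deg < 90,
            exposure_decay_m > 0,
            cliff_slope_deg > 0, cliff_slope_deg < 90,
            fit_cell_m > 0, map_cell_m > 0)
  structure(as.list(environment()), class = "terrain_config")
}

#' Co-registered predictor stack
#'
#' A named list of `crast` layers sharing one grid geometry. The canonical
#' twelve-layer set is built by [build_predictors()].
#'
#' @param layers named list of `crast` objects.
#' @export
pred_stack <- function(layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            all(vapply(layers, is_crast, TRUE)))
  ref <- layers[[1]]
  for (l in layers) cr_check_same_geom(ref, l)
  structure(list(layers = layers, cell_m = ref$cell_m,
                 xmin = ref$xmin, ymin = ref$ymin),
            class = "pred_stack")
}

#' @export
print.pred_stack <- function(x, ...) {
  cat(sprintf("<pred_stack> %d layers, %d x %d cells @ %g m\n  %s\n",
              length(x$layers), nrow(x$layers[[1]]$v), ncol(x$layers[[1]]$v),
              x$cell_m, paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Predictor stack as a samples-by-variables tibble
#'
#' One row per cell valid in the first layer; columns `row`, `col`, `x`, `y`
#' plus one per layer.
#' @param x a `pred_stack`.
#' @param ... unused.
#' @method as_tibble pred_stack
#' @export
as_tibble.pred_stack <- function(x, ...) {
  v1 <- x$layers[[1]]$v
  idx <- which(!is.na(v1))
  out <- cr_coords(x$layers[[1]], row(v1)[idx], col(v1)[idx])
  for (nm in names(x$layers)) out[[nm]] <- x$layers[[nm]]$v[idx]
  out
}

# Horn 3x3 neighborhood with replicate fill: missing neighbors (grid edge or
# sea) take the focal value, so gradients are computed from land only.
horn_neighbors <- function(m) {
  nb <- function(dr, dc) {
    s <- mat_shift(m, -dr, -dc, fill = NA)  # s[p] = m[p + (dr,dc)]
    s[is.na(s)] <- m[is.na(s)]
    s
  }
  list(a = nb(-1, -1), b = nb(-1, 0), c = nb(-1, 1),
       d = nb(0, -1),                 f = nb(0, 1),
       g = nb(1, -1),  h = nb(1, 0),  i = nb(1, 1))
}

#' Slope, aspect and aspect components (Horn's method)
#'
#' Slope and aspect from Horn 8-neighbour gradients on the 3 x 3 stencil;
#' aspect is in radians clockwise from north, as the downslope azimuth, and
#' is undefined (NA) where slope is zero. `EASTNESS = sin(aspect)` and
#' `NORTHNESS = cos(aspect)` (0 where aspect is undefined).
#'
#' @param dem elevation `crast`.
#' @return list of `crast`: `SLOPE_DEG`, `aspect` (radians), `EASTNESS`,
#'   `NORTHNESS`.
#' @export
slope_aspect <- function(dem) {
  stopifnot(is_crast(dem))
  m <- dem$v
  if (nrow(m) < 3 || ncol(m) < 3) stop("DEM must be at least 3 x 3")
  nb <- horn_neighbors(m)
  gx <- ((nb$c + 2 * nb$f + nb$i) - (nb$a + 2 * nb$d + nb$g)) / (8 * dem$cell_m)
  gy <- ((nb$a + 2 * nb$b + nb$c) - (nb$g + 2 * nb$h + nb$i)) / (8 * dem$cell_m)
  slope <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  aspect <- atan2(-gx, -gy) %% (2 * pi)
  aspect[slope == 0] <- NA
  east <- sin(aspect); north <- cos(aspect)
  east[is.na(east) & !is.na(slope)] <- 0
  north[is.na(north) & !is.na(slope)] <- 0
  sea <- is.na(m)
  slope[sea] <- NA; aspect[sea] <- NA; east[sea] <- NA; north[sea] <- NA
  wrap <- function(v) crast(v, dem$cell_m, dem$xmin, dem$ymin)
  list(SLOPE_DEG = wrap(slope), aspect = wrap(aspect),
       EASTNESS = wrap(east), NORTHNESS = wrap(north))
}

#' Terrain ruggedness index
#'
#' Per cell, the root-mean-square of elevation differences to the available
#' 8 neighbours (Riley-style TRI); edge and coastal cells use the neighbours
#' they have.
#' @param dem elevation `crast`.
#' @export
terrain_tri <- function(dem) {
  stopifnot(is_crast(dem))
  m <- dem$v
  if (nrow(m) < 3 || ncol(m) < 3) stop("DEM must be at least 3 x 3")
  ss <- matrix(0, nrow(m), ncol(m)); cnt <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    s <- mat_shift(m, -dr, -dc, fill = NA)
    ok <- !is.na(s) & !is.na(m)
    ss[ok] <- ss[ok] + (m[ok] - s[ok])^2
    cnt <- cnt + ok
  }
  out <- ifelse(cnt > 0, sqrt(ss / pmax(cnt, 1)), NA)
  out[is.na(m)] <- NA
  crast(out, dem$cell_m, dem$xmin, dem$ymin)
}

#' Topographic position index
#'
#' Elevation minus the mean elevation of other land cells within a circular
#' window; NoData where the window holds no other land cell.
#' @param dem elevation `crast`.
#' @param radius_m window radius in metres (>= one cell).
#' @export
terrain_tpi <- function(dem, radius_m = 90) {
  stopifnot(is_crast(dem), radius_m >= dem$cell_m)
  mu <- focal_disc(dem$v, radius_m / dem$cell_m, "mean", include_center = FALSE)
  out <- dem$v - mu
  crast(out, dem$cell_m, dem$xmin, dem$ymin)
}

#' Euclidean distance to the shoreline
#'
#' Exact Euclidean distance transform (EBImage) from each land-cell centre to
#' the land/sea interface; cells adjacent to sea get `cell_m / 2` and the
#' value is floored at zero. Beyond-grid area counts as sea.
#' @param dem elevation `crast` (sea = NA).
#' @export
dist_coast <- function(dem) {
  stopifnot(is_crast(dem))
  land <- !is.na(dem$v)
  if (!any(land)) stop("no land cells")
  nr <- nrow(land); nc <- ncol(land)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- land * 1
  d <- EBImage::imageData(EBImage::distmap(pad, metric = "euclidean"))
  d <- d[2:(nr + 1), 2:(nc + 1)] * dem$cell_m
  out <- pmax(d - dem$cell_m / 2, 0)
  out[!land] <- NA
  crast(out, dem$cell_m, dem$xmin, dem$ymin)
}

#' Heat-load index (McCune-Keon)
#'
#' Aspect-folded insolation proxy. Aspect is folded about the SW axis,
#' `A = |pi - |aspect - 5 pi / 4||`, and the published exponential equation
#' `HL = exp(-1.467 + 1.582 cos(L) cos(S) - 1.500 cos(A) sin(S) cos(L)
#' - 0.262 sin(L) sin(S) + 0.607 sin(A) sin(S))` is evaluated with latitude
#' `L`, slope `S` and folded aspect `A` in radians. Where aspect is
#' undefined (flat cells) the aspect terms vanish because `sin(S) = 0`.
#'
#' @param slope_deg slope `crast` (degrees).
#' @param aspect aspect `crast` (radians clockwise from north).
#' @param latitude_deg latitude in (-90, 90).
#' @export
heat_load <- function(slope_deg, aspect, latitude_deg = 37.5) {
  stopifnot(is_crast(slope_deg), is_crast(aspect),
            latitude_deg > -90, latitude_deg < 90)
  cr_check_same_geom(slope_deg, aspect)
  S <- slope_deg$v * pi / 180
  A <- aspect$v
  A[is.na(A)] <- pi / 2  # neutral; multiplied by sin(S) = 0 at flat cells
  A <- abs(pi - abs(A - 5 * pi / 4))
  L <- latitude_deg * pi / 180
  hl <- exp(-1.467 + 1.582 * cos(L) * cos(S) -
            1.500 * cos(A) * sin(S) * cos(L) -
            0.262 * sin(L) * sin(S) + 0.607 * sin(A) * sin(S))
  hl[is.na(slope_deg$v)] <- NA
  crast(hl, slope_deg$cell_m, slope_deg$xmin, slope_deg$ymin)
}

rescale01 <- function(v) {
  rng <- range(v, na.rm = TRUE)
  if (!is.finite(rng[1]) || rng[2] == rng[1]) return(v * 0)
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Topographic wetness proxy
#'
#' `TWI_APPROX = -(relief_01 + slope_01)` where relief is the max-min
#' elevation range in a circular window and both terms are min-max rescaled
#' to `[0, 1]` island-wide before summation (the rescale makes the two terms
#' commensurate and is this package's declared convention; the proxy
#' deliberately avoids the classic flow-accumulation form). Higher values =
#' wetter; the island-wide maximum is 0.
#'
#' @param dem elevation `crast`.
#' @param slope_deg slope `crast` (degrees).
#' @param relief_radius_m window radius, metres.
#' @export
twi_proxy <- function(dem, slope_deg, relief_radius_m = 90) {
  stopifnot(is_crast(dem), is_crast(slope_deg), relief_radius_m >= dem$cell_m)
  cr_check_same_geom(dem, slope_deg)
  rad <- relief_radius_m / dem$cell_m
  relief <- focal_disc(dem$v, rad, "max") - focal_disc(dem$v, rad, "min")
  out <- -(rescale01(relief) + rescale01(slope_deg$v))
  out[is.na(dem$v)] <- NA
  crast(out, dem$cell_m, dem$xmin, dem$ymin)
}

#' Coastal exposure, edge slope and cliff proximity
#'
#' Declared conventions for the three coastal metrics:
#' * `WAVE_EXP = exp(-DIST_COAST_M / decay) * openness`, where openness is
#'   the fraction of 16 compass rays from the cell that reach sea within the
#'   decay length;
#' * `EDGE_SLOPE` = mean slope of shoreline-adjacent land cells within the
#'   decay length (0 where none);
#' * `CLIFF_NEAR` = Euclidean distance to the nearest cell with slope at or
#'   above the cliff threshold (finite sentinel, 10 x the grid extent, when
#'   the landscape has no cliff cell).
#'
#' @param dem elevation `crast`.
#' @param slope_deg slope `crast`.
#' @param dist_coast_r distance-to-coast `crast` from [dist_coast()].
#' @param config a [terrain_config()].
#' @return list of `crast`: `WAVE_EXP`, `EDGE_SLOPE`, `CLIFF_NEAR`.
#' @export
coastal_exposure <- function(dem, slope_deg, dist_coast_r,
                             config = terrain_config()) {
  stopifnot(is_crast(dem))
  cr_check_same_geom(dem, slope_deg); cr_check_same_geom(dem, dist_coast_r)
  land <- !is.na(dem$v)
  sea <- !land
  cm <- dem$cell_m
  decay <- config$exposure_decay_m
  n_steps <- max(1, floor(decay / cm))
  reached_n <- matrix(0, nrow(sea), ncol(sea))
  for (k in 0:15) {
    th <- 2 * pi * k / 16
    reached <- matrix(FALSE, nrow(sea), ncol(sea))
    for (j in seq_len(n_steps)) {
      dr <- -round(j * cos(th)); dc <- round(j * sin(th))
      s <- mat_shift(sea, -dr, -dc, fill = TRUE)  # s[p] = sea at p + (dr,dc)
      reached <- reached | s
    }
    reached_n <- reached_n + reached
  }
  openness <- reached_n / 16
  wave <- exp(-dist_coast_r$v / decay) * openness
  wave[!land] <- NA

  edge <- land & dist_coast_r$v < cm
  es_src <- ifelse(edge, slope_deg$v, NA)
  es <- focal_disc(es_src, decay / cm, "mean")
  es[is.na(es)] <- 0
  es[!land] <- NA

  cliff <- land & !is.na(slope_deg$v) & slope_deg$v >= config$cliff_slope_deg
  if (any(cliff)) {
    d <- EBImage::imageData(
      EBImage::distmap(1 - cliff * 1, metric = "euclidean")) * cm
  } else {
    d <- matrix(10 * max(dim(dem$v)) * cm, nrow(dem$v), ncol(dem$v))
  }
  d[!land] <- NA
  wrap <- function(v) crast(v, cm, dem$xmin, dem$ymin)
  list(WAVE_EXP = wrap(wave), EDGE_SLOPE = wrap(es), CLIFF_NEAR = wrap(d))
}

#' Aggregate a stack to the fit scale
#'
#' Block-mean aggregation from the native mapping scale to the fitting scale
#' (`fit_cell_m` must be an integer multiple of the native cell size).
#' Aggregated cells average the contributing land cells; blocks with no land
#' are NoData. The same coefficient vector is evaluated per cell on either
#' scale, so no back-transformation is needed beyond predicting on the
#' native stack.
#'
#' @param stack a `pred_stack` at the native scale.
#' @param fit_cell_m target cell size (m).
#' @return list with `fit` (aggregated `pred_stack`) and `map` (the input).
#' @export
scale_transfer <- function(stack, fit_cell_m) {
  stopifnot(inherits(stack, "pred_stack"))
  f <- fit_cell_m / stack$cell_m
  if (abs(f - round(f)) > 1e-9) {
    stop("fit_cell_m must be an integer multiple of the native cell size")
  }
  f <- as.integer(round(f))
  agg1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    nr2 <- ceiling(nr / f); nc2 <- ceiling(nc / f)
    s <- matrix(0, nr2, nc2); cnt <- matrix(0, nr2, nc2)
    for (i in seq_len(f)) for (j in seq_len(f)) {
      ri <- seq(i, nr, by = f); ci <- seq(j, nc, by = f)
      sub <- matrix(NA_real_, nr2, nc2)
      sub[seq_along(ri), seq_along(ci)] <- m[ri, ci]
      ok <- !is.na(sub)
      s[ok] <- s[ok] + sub[ok]
      cnt <- cnt + ok
    }
    ifelse(cnt > 0, s / cnt, NA)
  }
  nr <- nrow(stack$layers[[1]]$v)
  nr2 <- ceiling(nr / f)
  ymin2 <- stack$ymin - (nr2 * f - nr) * stack$cell_m
  layers <- lapply(stack$layers, function(l)
    crast(agg1(l$v), fit_cell_m, stack$xmin, ymin2))
  list(fit = pred_stack(layers), map = stack)
}

#' Build the canonical 12-layer predictor stack
#'
#' Derives `ELEV_M`, `SLOPE_DEG`, `TRI`, `TPI`, `EASTNESS`, `NORTHNESS`,
#' `DIST_COAST_M`, `HEAT_LOAD`, `TWI_APPROX`, `WAVE_EXP`, `EDGE_SLOPE` and
#' `CLIFF_NEAR` from a DEM at its native resolution.
#'
#' @param dem elevation `crast` (sea = NA).
#' @param config a [terrain_config()].
#' @return a `pred_stack`.
#' @export
build_predictors <- function(dem, config = terrain_config()) {
  sa <- slope_aspect(dem)
  dc <- dist_coast(dem)
  hl <- heat_load(sa$SLOPE_DEG, sa$aspect, config$latitude_deg)
  twi <- twi_proxy(dem, sa$SLOPE_DEG, config$relief_radius_m)
  ce <- coastal_exposure(dem, sa$SLOPE_DEG, dc, config)
  pred_stack(list(
    ELEV_M = dem,
    SLOPE_DEG = sa$SLOPE_DEG,
    TRI = terrain_tri(dem),
    TPI = terrain_tpi(dem, config$tpi_radius_m),
    EASTNESS = sa$EASTNESS,
    NORTHNESS = sa$NORTHNESS,
    DIST_COAST_M = dc,
    HEAT_LOAD = hl,
    TWI_APPROX = twi,
    WAVE_EXP = ce$WAVE_EXP,
    EDGE_SLOPE = ce$EDGE_SLOPE,
    CLIFF_NEAR = ce$CLIFF_NEAR
  ))
}
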