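test_that("slope and aspect have the expected gradient geometry", {
  flat <- toy_dem(matrix(TRUE, 5, 5), elev = 10)
  sa <- slope_aspect(flat)
  expect_true(all(sa$SLOPE_DEG$v == 0))
  expect_true(all(is.na(sa$aspect$v)))
  expect_true(all(sa$EASTNESS$v == 0))
  # east-rising plane z = x faces west
  n <- 5; cm <- 5
  z <- matrix(rep((seq_len(n) - 0.5) * cm, each = n), n, n)
  sa2 <- slope_aspect(crast(z, cm))
  expect_equal(unname(sa2$SLOPE_DEG$v[3, 3]), 45)
  expect_equal(unname(sa2$EASTNESS$v[3, 3]), -1)
  expect_equal(unname(sa2$NORTHNESS$v[3, 3]), 0, tolerance = 1e-12)
  expect_error(slope_aspect(toy_crast(matrix(1, 1, 1))), "3 x 3")
})

test_that("slope matches a direct Horn-formula oracle on a random DEM", {
  set.seed(5)
  z <- matrix(runif(25, 0, 20), 5, 5)
  cm <- 5
  sa <- slope_aspect(crast(z, cm))
  # interior cells: classic 3x3 Horn kernel evaluated cell by cell
  for (i in 2:4) for (j in 2:4) {
    w <- z[(i - 1):(i + 1), (j - 1):(j + 1)]
    gx <- ((w[1, 3] + 2 * w[2, 3] + w[3, 3]) -
           (w[1, 1] + 2 * w[2, 1] + w[3, 1])) / (8 * cm)
    gy <- ((w[1, 1] + 2 * w[1, 2] + w[1, 3]) -
           (w[3, 1] + 2 * w[3, 2] + w[3, 3])) / (8 * cm)
    expect_equal(sa$SLOPE_DEG$v[i, j], atan(sqrt(gx^2 + gy^2)) * 180 / pi)
    expect_equal(sa$aspect$v[i, j], atan2(-gx, -gy) %% (2 * pi))
  }
})

test_that("TRI equals the brute-force neighbour loop", {
  expect_true(all(terrain_tri(toy_dem(matrix(TRUE, 4, 4), 3))$v == 0))
  z <- matrix(0, 3, 3); z[2, 2] <- 1
  expect_equal(terrain_tri(crast(z, 5))$v[2, 2], 1)
  set.seed(8)
  z <- matrix(runif(25, 0, 10), 5, 5)
  got <- terrain_tri(crast(z, 5))$v
  for (i in 1:5) for (j in 1:5) {
    diffs <- c()
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      r <- i + di; c <- j + dj
      if (r >= 1 && r <= 5 && c >= 1 && c <= 5) {
        diffs <- c(diffs, z[i, j] - z[r, c])
      }
    }
    expect_equal(got[i, j], sqrt(mean(diffs^2)))
  }
})

test_that("TPI equals the exhaustive circular-window oracle", {
  expect_true(all(abs(terrain_tpi(toy_dem(matrix(TRUE, 7, 7), 4),
                                  radius_m = 10)$v) < 1e-12))
  z <- matrix(0, 5, 5); z[3, 3] <- 7
  expect_gt(terrain_tpi(crast(z, 5), 10)$v[3, 3], 0)
  set.seed(13)
  z <- matrix(runif(49, 0, 30), 7, 7)
  cm <- 5; rad <- 2 * cm
  got <- terrain_tpi(crast(z, cm), rad)$v
  for (i in 1:7) for (j in 1:7) {
    vals <- c()
    for (r in 1:7) for (c in 1:7) {
      if (r == i && c == j) next
      if ((r - i)^2 + (c - j)^2 <= (rad / cm)^2) vals <- c(vals, z[r, c])
    }
    expect_equal(got[i, j], z[i, j] - mean(vals))
  }
})

test_that("distance to coast follows center-to-boundary geometry", {
  # 1-D strip: sea everywhere except columns 5:20 of a wide band; the middle
  # row is far from the top/bottom shores, so distances are set by the west
  # edge of the land block
  land <- matrix(FALSE, 21, 21)
  land[, 5:21] <- TRUE
  dc <- dist_coast(toy_dem(land, 10, cell_m = 5))
  expect_equal(unname(dc$v[11, 5:8]), c(2.5, 7.5, 12.5, 17.5))
})

test_that("distance transform equals brute-force nearest-sea search", {
  set.seed(21)
  land <- matrix(runif(400) < 0.6, 20, 20)
  land[10, 10] <- TRUE
  dem <- toy_dem(land, 5, cell_m = 5)
  got <- dist_coast(dem)$v
  # oracle: nearest sea-cell center (grid padded with a sea ring), minus
  # half a cell, floored at zero
  sea <- which(!land, arr.ind = TRUE)
  ring <- rbind(expand.grid(row = c(0, 21), col = 0:21),
                expand.grid(row = 0:21, col = c(0, 21)))
  sea <- rbind(sea, as.matrix(ring))
  for (idx in which(land)) {
    i <- row(land)[idx]; j <- col(land)[idx]
    d <- min(sqrt((sea[, 1] - i)^2 + (sea[, 2] - j)^2)) * 5
    expect_equal(got[i, j], max(d - 2.5, 0))
  }
})

test_that("distance to coast is 1-Lipschitz on the island", {
  dc <- demo_island()$stack$layers$DIST_COAST_M
  v <- dc$v
  right <- abs(v[, -1] - v[, -ncol(v)])
  down <- abs(v[-1, ] - v[-nrow(v), ])
  expect_lte(max(right, na.rm = TRUE), dc$cell_m + 1e-9)
  expect_lte(max(down, na.rm = TRUE), dc$cell_m + 1e-9)
})

test_that("heat load matches the published equation and its symmetries", {
  n <- 3
  mk <- function(slope, aspect) {
    list(slope = toy_crast(matrix(slope, n, n)),
         aspect = toy_crast(matrix(aspect, n, n)))
  }
  # flat terrain: aspect drops out
  f1 <- heat_load(mk(0, 0)$slope, toy_crast(matrix(NA_real_, n, n)), 37.5)
  f2 <- heat_load(mk(0, 0)$slope, mk(0, pi)$aspect, 37.5)
  expect_equal(f1$v, f2$v)
  # SW-facing beats NE-facing at equal slope
  sw <- heat_load(mk(20, 5 * pi / 4)$slope, mk(20, 5 * pi / 4)$aspect, 37.5)
  ne <- heat_load(mk(20, pi / 4)$slope, mk(20, pi / 4)$aspect, 37.5)
  expect_gt(sw$v[2, 2], ne$v[2, 2])
  # scalar oracle: latitude 37.5, slope 20 deg, aspect south (180 deg)
  got <- heat_load(mk(20, pi)$slope, mk(20, pi)$aspect, 37.5)$v[1, 1]
  L <- 37.5 * pi / 180; S <- 20 * pi / 180
  A <- abs(pi - abs(pi - 5 * pi / 4))
  want <- exp(-1.467 + 1.582 * cos(L) * cos(S) -
              1.5 * cos(A) * sin(S) * cos(L) -
              0.262 * sin(L) * sin(S) + 0.607 * sin(A) * sin(S))
  expect_equal(got, want)
})

test_that("wetness proxy ranks valleys above ridges and matches its oracle", {
  flat <- toy_dem(matrix(TRUE, 9, 9), 5)
  sa <- slope_aspect(flat)
  tw <- twi_proxy(flat, sa$SLOPE_DEG, 10)
  expect_true(all(tw$v == 0))
  # 9x9 toy: oracle recomputes window relief and the island-wide rescale
  set.seed(3)
  z <- matrix(runif(81, 0, 12), 9, 9)
  dem <- crast(z, 5)
  sl <- slope_aspect(dem)$SLOPE_DEG
  got <- twi_proxy(dem, sl, 10)$v
  relief <- matrix(NA_real_, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    vals <- c()
    for (r in 1:9) for (c in 1:9) {
      if ((r - i)^2 + (c - j)^2 <= 4) vals <- c(vals, z[r, c])
    }
    relief[i, j] <- max(vals) - min(vals)
  }
  sc <- function(v) (v - min(v)) / (max(v) - min(v))
  expect_equal(got, -(sc(relief) + sc(sl$v)), tolerance = 1e-12)
  # steep ridge vs flat valley on the island
  isl <- demo_island()
  twv <- isl$stack$layers$TWI_APPROX$v
  slv <- isl$stack$layers$SLOPE_DEG$v
  steep <- which(slv > quantile(slv, 0.95, na.rm = TRUE))
  gentle <- which(slv < quantile(slv, 0.05, na.rm = TRUE))
  expect_gt(mean(twv[gentle]), mean(twv[steep]))
})

test_that("coastal exposure conventions behave at their limits", {
  # single-cell island: every ray reaches sea at once
  land <- matrix(FALSE, 5, 5); land[3, 3] <- TRUE
  dem <- toy_dem(land, 1, cell_m = 5)
  sa <- slope_aspect(dem)
  ce <- coastal_exposure(dem, sa$SLOPE_DEG, dist_coast(dem),
                         terrain_config(exposure_decay_m = 200))
  expect_equal(ce$WAVE_EXP$v[3, 3], exp(-2.5 / 200), tolerance = 1e-9)
  # interior cells beyond ~5 decay lengths are dark
  isl <- demo_island()
  ce2 <- coastal_exposure(isl$dem, isl$stack$layers$SLOPE_DEG,
                          isl$stack$layers$DIST_COAST_M,
                          terrain_config(exposure_decay_m = 50))
  far <- isl$stack$layers$DIST_COAST_M$v > 250
  expect_lt(max(ce2$WAVE_EXP$v[far], na.rm = TRUE), 0.01)
})

test_that("cliff distance equals exhaustive search on a toy island", {
  land <- matrix(TRUE, 7, 7)
  z <- matrix(5, 7, 7)
  dem <- crast(z, 5)
  sa <- slope_aspect(dem)
  sl <- sa$SLOPE_DEG
  sl$v[2, 6] <- 45  # one cliff cell
  ce <- coastal_exposure(dem, sl, dist_coast(dem), terrain_config())
  for (i in 1:7) for (j in 1:7) {
    expect_equal(ce$CLIFF_NEAR$v[i, j],
                 sqrt((i - 2)^2 + (j - 6)^2) * 5)
  }
  # no cliffs anywhere: finite sentinel
  ce0 <- coastal_exposure(dem, sa$SLOPE_DEG, dist_coast(dem), terrain_config())
  expect_true(all(is.finite(ce0$CLIFF_NEAR$v)))
  expect_gt(min(ce0$CLIFF_NEAR$v), 7 * 5)
})

test_that("scale transfer is block-mean aggregation with NoData awareness", {
  const <- pred_stack(list(A = toy_crast(matrix(3, 6, 6), 5)))
  agg <- scale_transfer(const, 15)$fit
  expect_true(all(agg$layers$A$v == 3))
  expect_equal(dim(agg$layers$A$v), c(2, 2))
  set.seed(4)
  z <- matrix(runif(36), 6, 6); z[1, 2] <- NA
  st <- pred_stack(list(A = crast(z, 5)))
  agg2 <- scale_transfer(st, 15)$fit
  blk <- z[1:3, 1:3]
  expect_equal(agg2$layers$A$v[1, 1], mean(blk, na.rm = TRUE))
  expect_equal(agg2$layers$A$v[2, 2], mean(z[4:6, 4:6]))
  expect_error(scale_transfer(st, 12), "integer multiple")
})

test_that("the twelve canonical layers are co-registered and finite on land", {
  isl <- demo_island()
  st <- isl$stack
  expect_setequal(names(st$layers),
                  c("ELEV_M", "SLOPE_DEG", "TRI", "TPI", "EASTNESS",
                    "NORTHNESS", "DIST_COAST_M", "HEAT_LOAD", "TWI_APPROX",
                    "WAVE_EXP", "EDGE_SLOPE", "CLIFF_NEAR"))
  land <- !is.na(isl$dem$v)
  for (nm in names(st$layers)) {
    expect_true(all(is.finite(st$layers[[nm]]$v[land])), label = nm)
    expect_true(all(is.na(st$layers[[nm]]$v[!land])), label = nm)
  }
  en <- st$layers$EASTNESS$v[land]^2 + st$layers$NORTHNESS$v[land]^2
  expect_lte(max(en), 1 + 1e-9)
  expect_true(all(st$layers$DIST_COAST_M$v[land] >= 0))
  expect_true(all(st$layers$SLOPE_DEG$v[land] >= 0 &
                    st$layers$SLOPE_DEG$v[land] <= 90))
  # TPI of a closed landmass is near zero-mean for large windows
  tpi <- st$layers$TPI$v[land]
  expect_lt(abs(mean(tpi)), 0.05 * sd(tpi))
})
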