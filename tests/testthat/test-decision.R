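test_that("threshold menu follows its quantile and Youden conventions", {
  bgc <- rep(0.37, 50)
  expect_equal(compute_threshold("spec0980", background_preds = bgc)$theta, 0.37)
  expect_equal(compute_threshold("tp10",
                                 presence_preds = seq(0.1, 1, 0.1))$theta, 0.19)
  # perfectly separated: midpoint strictly between the classes
  th <- compute_threshold("maxtss", presence_preds = c(0.7, 0.8, 0.9),
                          background_preds = c(0.1, 0.2, 0.3))$theta
  expect_equal(th, (0.7 + 0.3) / 2)
  expect_gt(th, 0.3); expect_lt(th, 0.7)
  expect_equal(compute_threshold("balanced_cv",
                                 fold_thresholds = c(0.2, 0.5, 0.4))$theta, 0.4)
  cov <- compute_threshold("coverage_target",
                           belt_presence_preds = seq(0.05, 1, length.out = 20),
                           coverage = 0.9)$theta
  expect_gte(mean(seq(0.05, 1, length.out = 20) >= cov), 0.9)
  expect_error(compute_threshold("spec0980"), "nonempty")
})

test_that("spec0980 guarantees 0.98 specificity on the training background", {
  set.seed(24)
  bg <- runif(744)
  th <- compute_threshold("spec0980", background_preds = bg)$theta
  expect_gte(mean(bg < th), 0.98)
})

test_that("binarization is inclusive and monotone in the threshold", {
  s <- toy_crast(matrix(c(0.1, 0.5, NA, 0.9), 2, 2))
  b <- binarize(s, 0.5)
  expect_equal(b$v[2, 1], 1)   # exactly at threshold: included
  expect_true(is.na(b$v[1, 2]))
  expect_equal(cr_area(binarize(s, 0), km2 = FALSE), 75)
  expect_equal(cr_area(binarize(s, 1 + 1e-9), km2 = FALSE), 0)
  areas <- vapply(c(0, 0.3, 0.6, 0.95),
                  function(t) cr_area(binarize(s, t)), 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("coastal belts follow Q90 and nest with width", {
  isl <- demo_island()
  dcr <- isl$stack$layers$DIST_COAST_M
  d <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  belt <- coastal_belt(d, dcr, q = 0.90)
  expect_equal(belt$width_m, unname(quantile(d, 0.9)))
  b60 <- coastal_belt(dist_coast_r = dcr, width_m = 60)
  b90 <- coastal_belt(dist_coast_r = dcr, width_m = 90)
  b120 <- coastal_belt(dist_coast_r = dcr, width_m = 120)
  expect_true(all(which(b60$mask$v == 1) %in% which(b90$mask$v == 1)))
  expect_true(all(which(b90$mask$v == 1) %in% which(b120$mask$v == 1)))
  expect_error(coastal_belt(c(1, 2), dcr), "at least 5")
  # presences hugging the shore: belt collapses to shoreline-adjacent cells
  shore <- coastal_belt(rep(2.5, 6), dcr, q = 0.9)
  expect_equal(shore$width_m, 2.5)
  expect_true(all(dcr$v[shore$mask$v == 1 & !is.na(shore$mask$v)] <= 2.5))
})

test_that("MMU filter equals flood-fill labelling on random binaries", {
  # two diagonal cells form one 8-connected component of size 2: removed
  v <- matrix(0, 4, 4); v[1, 1] <- 1; v[2, 2] <- 1
  out <- mmu_filter(toy_crast(v), min_cells = 3)
  expect_equal(sum(out$v), 0)
  # L-shaped 3-cell patch is retained
  v2 <- matrix(0, 4, 4); v2[2, 2] <- 1; v2[3, 2] <- 1; v2[3, 3] <- 1
  expect_equal(sum(mmu_filter(toy_crast(v2), 3)$v), 3)
  set.seed(25)
  r <- toy_crast(matrix(as.numeric(runif(900) < 0.4), 30, 30))
  for (mc in c(2, 4)) {
    got <- mmu_filter(r, mc)$v
    lab <- bfs_label(r$v == 1, connectivity = 8)
    keep <- as.integer(names(which(table(lab[!is.na(lab)]) >= mc)))
    want <- ifelse(!is.na(lab) & lab %in% keep, 1, 0)
    expect_equal(got, want)
  }
})

test_that("CORE products report area, coverage and zero post-belt leakage", {
  # toy: 5 m cells, three suitable cells inside the belt
  s <- matrix(0.1, 8, 8)
  s[4, 4:6] <- 0.9
  suit <- toy_crast(s, cell_m = 5)
  dcr <- toy_crast(matrix(rep(seq(2.5, 37.5, by = 5), each = 8), 8, 8))
  belt <- coastal_belt(dist_coast_r = dcr, width_m = 30)
  prod <- core_map(suit, 0.5, belt, min_cells = 3)
  expect_equal(prod$area_km2, 75 / 1e6)   # 3 cells x 25 m^2
  expect_equal(prod$leakage_post_km2, 0)
  # full coverage when everything is suitable and belt covers all
  allb <- coastal_belt(dist_coast_r = dcr, width_m = 100)
  sites <- tibble::tibble(x = c(7.5, 22.5), y = c(17.5, 22.5))
  p2 <- core_map(toy_crast(matrix(0.9, 8, 8), 5), 0.1, allb, 1, sites)
  expect_equal(p2$coverage, 1)
  # pre-belt leakage equals the enumeration oracle
  lk <- leakage_area(suit, 0.5, belt$mask)
  hot <- s >= 0.5; outside <- dcr$v > 30
  expect_equal(lk, sum(hot & outside) * 25 / 1e6)
  expect_equal(leakage_area(suit, 1.1, belt$mask), 0)
  expect_equal(leakage_area(suit, 0.5,
                            coastal_belt(dist_coast_r = dcr, width_m = 50)$mask),
               0)
})

test_that("area band arithmetic matches the min-max definition", {
  band <- area_band(c(0.930, 1.593))
  expect_equal(band$spread, 0.663)
  expect_equal(band$percent_increase, 71.3)
  expect_equal(area_band(5)$spread, 0)
})

test_that("belt/MMU sweep areas are monotone and never leak past the belt", {
  set.seed(26)
  s <- matrix(runif(900), 30, 30)
  suit <- toy_crast(s, 5)
  dcr <- toy_crast(matrix(rep(seq(2.5, by = 5, length.out = 30), each = 30),
                          30, 30), 5)
  sweep <- belt_mmu_sweep(suit, c(spec = 0.8, tss = 0.5), dcr,
                          belts_m = c(30, 60, 90), mmus = c(1, 3, 5))
  expect_true(sweep$monotone_mmu)
  expect_true(all(sweep$grid$leakage_post_km2 == 0))
  # nondecreasing in belt width at fixed rule and MMU
  g <- sweep$grid[order(sweep$grid$rule, sweep$grid$mmu, sweep$grid$belt_m), ]
  for (sp in split(g, list(g$rule, g$mmu))) {
    expect_true(all(diff(sp$area_km2) >= -1e-12))
  }
  # per-cell oracle for one combination
  one <- sweep$grid[sweep$grid$rule == "spec" & sweep$grid$belt_m == 60 &
                      sweep$grid$mmu == 3, ]
  binb <- (s >= 0.8) & (dcr$v <= 60)
  lab <- bfs_label(binb, 8)
  keep <- as.integer(names(which(table(lab[!is.na(lab)]) >= 3)))
  expect_equal(one$area_km2, sum(!is.na(lab) & lab %in% keep) * 25 / 1e6)
})

test_that("segment ranking orders candidates by rolling-median score", {
  land <- matrix(TRUE, 30, 30)
  dem <- toy_dem(land, 10, cell_m = 5)
  sh <- shoreline_from_dem(dem)
  # uniform scores: every segment a candidate, ties broken by index
  suit <- toy_crast(matrix(0.8, 30, 30), 5)
  dcr <- dist_coast(dem)
  belt <- coastal_belt(dist_coast_r = dcr, width_m = 20)
  seg <- segment_rank(sh$rings, suit, 0.5, belt, segment_len_m = 50)
  expect_equal(seg$rank, seq_len(nrow(seg)))
  expect_equal(seg$segment, sort(seg$segment))
  expect_true(all(seg$band[seg$rank <= ceiling(0.1 * nrow(seg))] == "top 10%"))
  # a single high-suitability stretch (the full north-west quadrant) tops
  # the ranking; it must span several consecutive segments to survive the
  # rolling median
  v <- matrix(0.2, 30, 30); v[1:20, 1:20] <- 0.9
  seg2 <- segment_rank(sh$rings, toy_crast(v, 5), 0.5, belt,
                       segment_len_m = 50)
  expect_gt(nrow(seg2), 0)
  expect_true(all(seg2$score >= 0.5))
  # candidates lie on the west or north edge, where the block meets the coast
  expect_true(all(seg2$x < 5 | seg2$y > 145))
  # no candidates: empty with a message
  expect_message(
    none <- segment_rank(sh$rings, toy_crast(matrix(0.1, 30, 30), 5),
                         0.5, belt, segment_len_m = 50),
    "no candidate")
  expect_equal(nrow(none), 0)
})
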