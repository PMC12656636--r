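test_that("feature expansion scales, squares and hinges as specified", {
  X <- data.frame(a = c(0, 5, 10), b = c(2, 4, 6))
  fe <- expand_features(X, "l")
  expect_equal(ncol(fe$design), 2)
  expect_true(all(fe$design >= 0 & fe$design <= 1))
  fe2 <- expand_features(X, "lq")
  expect_equal(ncol(fe2$design), 4)
  expect_equal(unname(fe2$design[, "a__q"]), unname(fe2$design[, "a__l"]^2))
  # hinge formula on 5 hand-picked points
  xs <- data.frame(a = c(0, 0.25, 0.5, 0.75, 1))
  feh <- expand_features(xs, "h", hinge_knots = 2)
  # forward knots 0, 0.5; reverse knots 0.5, 1
  expect_equal(unname(feh$design[, "a__hf0.5000"]),
               pmax(0, (xs$a - 0.5) / 0.5))
  expect_equal(unname(feh$design[, "a__hr0.5000"]),
               pmax(0, (0.5 - xs$a) / 0.5))
  expect_warning(expand_features(data.frame(a = 1:3, z = 1), "l"),
                 "zero-variance")
  # applying training scaling to new rows clamps mild extrapolation
  fe3 <- expand_features(data.frame(a = c(-10, 30), b = c(2, 6)), "l",
                         scaling = fe$scaling)
  expect_equal(unname(fe3$design[, "a__l"]), c(-0.1, 1.1))
})

test_that("penalty schedule interpolates the published class tables", {
  info <- tibble::tibble(column = c("x__l", "x__q", "x__hf"),
                         variable = "x", class = c("l", "q", "h"),
                         knot = NA_real_)
  sds <- c(0.2, 0.3, 0.25)
  b <- default_penalties(info, 28, sds, rm = 1)
  # independent oracle: interpolate the published tables directly
  b_l <- approx(c(0, 10, 30, 100), c(1, 1, 0.2, 0.05), 28)$y
  b_q <- approx(c(0, 10, 17, 30, 100), c(1.3, 0.8, 0.5, 0.25, 0.05), 28)$y
  expect_equal(unname(b), c(b_l * 0.2, b_q * 0.3, 0.5 * 0.25) / sqrt(28))
  expect_equal(unname(default_penalties(info, 28, sds, rm = 2)), unname(2 * b))
  expect_equal(unname(default_penalties(info, 28, c(0.2, 0, 0.25), 1))[2], 0)
  expect_error(default_penalties(info, 1, sds), "at least 2")
})

test_that("full shrinkage gives the uniform raw distribution and cloglog 0.632", {
  set.seed(10)
  pres <- data.frame(v = rnorm(25), w = rnorm(25))
  bg <- data.frame(v = rnorm(300), w = rnorm(300))   # same distribution
  # penalties far above any gradient: exact full shrinkage
  fit <- fit_maxent(pres, bg, model_config("lq", rm = 5), penalties = 10)
  expect_equal(fit$k, 0)
  expect_equal(fit$entropy, log(300), tolerance = 1e-6)
  raw <- predict(fit, bg, type = "raw")
  expect_equal(unname(raw), rep(1 / 300, 300), tolerance = 1e-9)
  cll <- predict(fit, bg, type = "cloglog")
  expect_equal(unname(cll), rep(1 - exp(-1), 300), tolerance = 1e-6)
})

test_that("unpenalized single-feature fit satisfies moment matching", {
  set.seed(11)
  pres <- data.frame(v = rnorm(40, 1.5, 0.5))
  bg <- data.frame(v = rnorm(500, 0, 1))
  fit <- fit_maxent(pres, bg, model_config("l"), tol = 1e-10,
                    penalties = c(v__l = 0))
  fe <- expand_features(rbind(pres, bg), "l")
  f_pres <- mean(fe$design[1:40, 1])
  raw_bg <- predict(fit, bg, type = "raw")
  f_model <- sum(raw_bg * fe$design[-(1:40), 1])
  expect_equal(f_model, f_pres, tolerance = 1e-5)
  expect_equal(sum(raw_bg), 1, tolerance = 1e-8)
})

test_that("optimizer objective is monotone and predictions are order-invariant", {
  set.seed(12)
  pres <- data.frame(a = rnorm(30, 1), b = runif(30))
  bg <- data.frame(a = rnorm(400), b = runif(400))
  fit <- fit_maxent(pres, bg, model_config("lq", rm = 1))
  expect_true(all(diff(fit$objective) <= 1e-12))
  p1 <- predict(fit, bg, type = "cloglog")
  shuffle <- sample(400)
  p2 <- predict(fit, bg[shuffle, ], type = "cloglog")
  expect_equal(p2, p1[shuffle])
  # cloglog is monotone in the link
  lk <- predict(fit, bg, type = "link")
  expect_equal(order(p1), order(lk))
})

test_that("spearman pruning drops rank-duplicated, keeps protected", {
  set.seed(13)
  x <- runif(200)
  X <- data.frame(x = x, x2 = x^2, n1 = rnorm(200), n2 = rnorm(200))
  kept <- spearman_prune(X, 0.7)
  expect_true(xor("x" %in% kept, "x2" %in% kept))
  expect_true(all(c("n1", "n2") %in% kept))
  kept2 <- spearman_prune(X, 0.7, protected = "x2")
  expect_true("x2" %in% kept2)
  expect_warning(spearman_prune(X[c("x", "x2")], 0.7,
                                protected = c("x", "x2")),
                 "protected")
})

test_that("VIF pruning follows the hand-computed removal sequence", {
  set.seed(14)
  n <- 300
  z <- rnorm(n)
  X <- data.frame(a = z + rnorm(n, 0, 0.1),       # a, b, c mutually collinear
                  b = z + rnorm(n, 0, 0.1),
                  c = z + rnorm(n, 0, 0.15),
                  d = rnorm(n), e = rnorm(n))
  vif_oracle <- function(df) {
    vapply(names(df), function(v) {
      r2 <- summary(lm(df[[v]] ~ ., data = df[setdiff(names(df), v)]))$r.squared
      1 / (1 - r2)
    }, 0)
  }
  # oracle: drop argmax VIF until all <= 5
  keep <- names(X)
  repeat {
    vf <- vif_oracle(X[keep])
    if (max(vf) <= 5) break
    keep <- setdiff(keep, names(which.max(vf)))
  }
  expect_equal(sort(vif_prune(X, 5)), sort(keep))
  # orthogonal columns all survive; duplicated column is dropped
  O <- data.frame(p = rnorm(50), q = rnorm(50))
  expect_setequal(vif_prune(O, 5), c("p", "q"))
  D <- data.frame(p = O$p, q = O$p, r = rnorm(50))
  expect_equal(length(suppressWarnings(vif_prune(D, 5))), 2)
  expect_error(suppressWarnings(vif_prune(D[c("p", "q")], 5,
                                          protected = c("p", "q"))),
               "perfect collinearity")
})

test_that("accessible masks nest and respect the distance ceiling", {
  isl <- demo_island()
  st <- isl$fit
  m300 <- accessible_mask(st, 300)
  m450 <- accessible_mask(st, 450)
  m600 <- accessible_mask(st, 600)
  in300 <- which(m300$v == 1)
  expect_true(all(in300 %in% which(m450$v == 1)))
  expect_true(all(which(m450$v == 1) %in% which(m600$v == 1)))
  expect_true(all(st$layers$DIST_COAST_M$v[in300] <= 300))
  mall <- accessible_mask(st, Inf)
  expect_equal(sum(mall$v == 1, na.rm = TRUE),
               sum(complete.cases(as_tibble(st))))
})

test_that("background sampling hits the target ratio and is seeded", {
  isl <- demo_island()
  mask <- accessible_mask(isl$fit, 300)
  bg <- sample_background(mask, 28, 25, seed = 3)
  expect_equal(nrow(bg), 700)
  expect_equal(attr(bg, "realized_ratio"), 25)
  bg2 <- sample_background(mask, 28, 25, seed = 3)
  expect_identical(bg, bg2)
  expect_equal(realized_ratio(744, 28), 26.6)
  expect_false(any(duplicated(paste(bg$row, bg$col))))
})

test_that("AICc follows the small-sample formula on the fitted likelihood", {
  set.seed(15)
  pres <- data.frame(a = rnorm(28, 1))
  bg <- data.frame(a = rnorm(300))
  fit <- fit_maxent(pres, bg, model_config("lq", rm = 1))
  ll <- sum(log(predict(fit, pres, type = "raw")))
  k <- fit$k
  expect_equal(aicc(fit, pres),
               2 * k - 2 * ll + 2 * k * (k + 1) / (28 - k - 1))
  # k = 2, n = 28, LL = -100 arithmetic checkpoint
  expect_equal(2 * 2 - 2 * (-100) + 2 * 2 * 3 / (28 - 3), 204.48)
  tiny <- pres[1:2, , drop = FALSE]
  expect_message(val <- aicc(fit, tiny), "undefined")
  expect_true(is.na(val))
})

test_that("model selection maximizes the robustness score deterministically", {
  set.seed(16)
  pres <- data.frame(a = rnorm(25, 1.2), b = runif(25))
  bg <- data.frame(a = rnorm(250), b = runif(250))
  s1 <- select_model_grid(pres, bg, classes_grid = c("l", "lq"),
                          rm_grid = c(1, 2), folds = 5, seed = 7)
  s2 <- select_model_grid(pres, bg, classes_grid = c("l", "lq"),
                          rm_grid = c(1, 2), folds = 5, seed = 7)
  expect_identical(s1$grid, s2$grid)
  expect_equal(s1$grid$robustness, s1$grid$auc_mean - 0.5 * s1$grid$auc_sd)
  expect_equal(s1$best$robustness, max(s1$grid$robustness))
  expect_equal(s1$grid$delta_aicc[which.min(s1$grid$aicc)], 0)
})
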