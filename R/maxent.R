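#' Model configuration
#'
#' Feature classes are any subset of `l` (linear), `q` (quadratic) and `h`
#' (hinge); `l` must accompany `q`. `rm` is the regularization multiplier
#' scaling every per-feature L1 penalty.
#'
#' @param feature_classes character vector or compact string (`"lq"`).
#' @param rm regularization multiplier in `[0.5, 5]`.
#' @param hinge_knots knots per hinge direction.
#' @param background_target_ratio target background:presence ratio.
#' @param mask_dist_m accessible-background distance from shore (m).
#' @param seed integer seed.
#' @export
model_config <- function(feature_classes = "lq", rm = 1, hinge_knots = 50,
                         background_target_ratio = 25, mask_dist_m = 300,
                         seed = 42) {
  feature_classes <- parse_classes(feature_classes)
  stopifnot(rm >= 0.5, rm <= 5, hinge_knots >= 2,
            background_target_ratio > 0, mask_dist_m >= 0)
  if ("q" %in% feature_classes && !"l" %in% feature_classes) {
    stop("feature class 'q' requires 'l'")
  }
  structure(list(feature_classes = feature_classes, rm = rm,
                 hinge_knots = hinge_knots,
                 background_target_ratio = background_target_ratio,
                 mask_dist_m = mask_dist_m, seed = seed),
            class = "model_config")
}

parse_classes <- function(x) {
  cl <- if (length(x) == 1 && nchar(x) > 1) strsplit(x, "")[[1]] else x
  cl <- unique(cl)
  if (length(cl) == 0 || !all(cl %in% c("l", "q", "h"))) {
    stop("feature classes must be drawn from {l, q, h}")
  }
  cl
}

#' Expand raw variables into the MaxEnt feature design matrix
#'
#' Variables are min-max scaled to `[0, 1]` using bounds from the training
#' sample; linear features are the scaled values, quadratic their squares,
#' and hinge features are forward `max(0, (x - t) / (1 - t))` and reverse
#' `max(0, (t - x) / t)` bases at equally spaced knots. When an existing
#' scaling is applied to new rows, scaled values are clamped to
#' `[-0.1, 1.1]` (mild extrapolation guard). Zero-variance variables are
#' excluded with a warning.
#'
#' @param X data frame or matrix of raw predictor variables.
#' @param classes feature classes (see [model_config()]).
#' @param scaling `NULL` to derive bounds from `X`, or the `scaling` element
#'   of a previous expansion.
#' @param hinge_knots knots per hinge direction.
#' @return list: `design` (matrix), `scaling` (per-variable min/max),
#'   `info` (tibble: column, variable, class, knot).
#' @export
expand_features <- function(X, classes = c("l", "q"), scaling = NULL,
                            hinge_knots = 50) {
  classes <- parse_classes(classes)
  X <- as.data.frame(X)
  if (is.null(scaling)) {
    mins <- vapply(X, min, 0, na.rm = TRUE)
    maxs <- vapply(X, max, 0, na.rm = TRUE)
    drop <- names(X)[maxs - mins <= 0]
    if (length(drop)) {
      warning("zero-variance variable(s) excluded: ", paste(drop, collapse = ", "))
      X <- X[setdiff(names(X), drop)]
      mins <- mins[names(X)]; maxs <- maxs[names(X)]
    }
    scaling <- list(min = mins, max = maxs)
    clamp <- FALSE
  } else {
    X <- X[names(scaling$min)]
    clamp <- TRUE
  }
  cols <- list(); info <- list()
  for (v in names(X)) {
    z <- (X[[v]] - scaling$min[[v]]) / (scaling$max[[v]] - scaling$min[[v]])
    if (clamp) z <- pmin(pmax(z, -0.1), 1.1)
    if ("l" %in% classes) {
      cols[[paste0(v, "__l")]] <- z
      info[[length(info) + 1]] <- tibble::tibble(
        column = paste0(v, "__l"), variable = v, class = "l", knot = NA_real_)
    }
    if ("q" %in% classes) {
      cols[[paste0(v, "__q")]] <- z^2
      info[[length(info) + 1]] <- tibble::tibble(
        column = paste0(v, "__q"), variable = v, class = "q", knot = NA_real_)
    }
    if ("h" %in% classes) {
      k <- hinge_knots
      tf <- (seq_len(k) - 1) / k     # forward knots in [0, 1)
      tr <- seq_len(k) / k           # reverse knots in (0, 1]
      for (t in tf) {
        nm <- sprintf("%s__hf%.4f", v, t)
        cols[[nm]] <- pmax(0, (z - t) / (1 - t))
        info[[length(info) + 1]] <- tibble::tibble(
          column = nm, variable = v, class = "h", knot = t)
      }
      for (t in tr) {
        nm <- sprintf("%s__hr%.4f", v, t)
        cols[[nm]] <- pmax(0, (t - z) / t)
        info[[length(info) + 1]] <- tibble::tibble(
          column = nm, variable = v, class = "h", knot = t)
      }
    }
  }
  design <- do.call(cbind, cols)
  rownames(design) <- NULL
  list(design = design, scaling = scaling, info = dplyr::bind_rows(info))
}

# published per-class penalty interpolation tables (sample size -> beta);
# the familiar MaxEnt defaults, frozen as data
penalty_table <- function(class) {
  switch(class,
         l = list(n = c(0, 10, 30, 100), b = c(1, 1, 0.2, 0.05)),
         q = list(n = c(0, 10, 17, 30, 100), b = c(1.3, 0.8, 0.5, 0.25, 0.05)),
         h = list(n = c(0, 1), b = c(0.5, 0.5)),
         stop("unknown feature class: ", class))
}

#' Default L1 penalty schedule
#'
#' `beta_j = rm * beta_class(n_presence) * sd_j / sqrt(n_presence)`, with the
#' class base penalty interpolated from the published MaxEnt default tables
#' (linear/quadratic interpolation points; hinge constant 0.5). `sd_j` is the
#' per-feature standard deviation over the reference (background) rows.
#'
#' @param info feature `info` tibble from [expand_features()].
#' @param n_presence number of presences (>= 2).
#' @param sd_per_feature per-feature sd, aligned with `info$column`.
#' @param rm regularization multiplier.
#' @return named penalty vector.
#' @export
default_penalties <- function(info, n_presence, sd_per_feature, rm = 1) {
  if (n_presence < 2) stop("need at least 2 presences")
  base <- vapply(info$class, function(cl) {
    tb <- penalty_table(cl)
    approx(tb$n, tb$b, xout = min(n_presence, max(tb$n)), rule = 2)$y
  }, 0)
  setNames(rm * base * sd_per_feature / sqrt(n_presence), info$column)
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fit a presence-background maximum-entropy model
#'
#' Minimises the convex penalised objective
#' `-(1/m) sum_presence(link) + log Z + sum_j beta_j |lambda_j|`, where
#' `Z = sum_background exp(link)`, by monotone FISTA (proximal gradient with
#' soft-thresholding, Nesterov momentum with restart, backtracking line
#' search). Convergence is declared when the penalised objective changes by
#' less than `tol`; non-convergence is an error carrying diagnostics.
#'
#' @param presence,background data frames of raw predictor variables (same
#'   columns); feature scaling is derived from their union, penalties from
#'   the background sd.
#' @param config a [model_config()].
#' @param tol objective-change convergence tolerance.
#' @param max_iter iteration cap.
#' @param penalties optional explicit penalty vector overriding the default
#'   schedule (length 1 recycled, or named per expanded feature); 0 gives an
#'   unpenalized maximum-entropy fit.
#' @return object of class `maxent_fit`: coefficients, scaling, `log_z`
#'   (over training background), entropy `H`, nonzero count `k`, and fitted
#'   raw distribution diagnostics.
#' @export
fit_maxent <- function(presence, background, config = model_config(),
                       tol = 1e-7, max_iter = 1e4, penalties = NULL) {
  stopifnot(nrow(presence) >= 2, nrow(background) >= 2)
  presence <- as.data.frame(presence); background <- as.data.frame(background)
  train <- rbind(presence, background)
  fe <- expand_features(train, config$feature_classes,
                        hinge_knots = config$hinge_knots)
  m <- nrow(presence)
  Xp <- fe$design[seq_len(m), , drop = FALSE]
  Xb <- fe$design[-seq_len(m), , drop = FALSE]
  sd_bg <- apply(Xb, 2, sd)
  beta <- default_penalties(fe$info, m, sd_bg, config$rm)
  if (!is.null(penalties)) {
    beta[] <- if (length(penalties) == 1) penalties else penalties[names(beta)]
    stopifnot(all(is.finite(beta)), all(beta >= 0))
  }

  p_means <- colMeans(Xp)
  smooth_f <- function(lam) {
    lk <- drop(Xb %*% lam)
    -sum(p_means * lam) + log_sum_exp(lk)
  }
  grad_f <- function(lam) {
    lk <- drop(Xb %*% lam)
    w <- exp(lk - log_sum_exp(lk))
    -p_means + drop(crossprod(Xb, w))
  }
  pen <- function(lam) sum(beta * abs(lam))
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

  lam <- rep(0, ncol(Xb)); y <- lam; tk <- 1; L <- 1
  F_cur <- smooth_f(lam) + pen(lam)
  trace_F <- F_cur
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    gy <- grad_f(y); fy <- smooth_f(y)
    repeat {
      cand <- soft(y - gy / L, beta / L)
      dlt <- cand - y
      if (smooth_f(cand) <= fy + sum(gy * dlt) + L / 2 * sum(dlt^2) + 1e-12) break
      L <- L * 2
    }
    F_new <- smooth_f(cand) + pen(cand)
    if (!is.finite(F_new) || F_new < -1e10) {
      stop("maxent objective unbounded: presences and background are ",
           "separable relative to the penalty (degenerate fit)")
    }
    if (F_new > F_cur) {            # monotone safeguard: restart momentum
      y <- lam; tk <- 1
      next
    }
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- cand + (tk - 1) / t_new * (cand - lam)
    lam <- cand; tk <- t_new
    if (abs(F_cur - F_new) < tol) { F_cur <- F_new; trace_F <- c(trace_F, F_new); converged <- TRUE; break }
    F_cur <- F_new; trace_F <- c(trace_F, F_new)
    L <- max(L / 2, 1e-3)
  }
  if (!converged) {
    stop(sprintf(
      "maxent fit did not converge in %d iterations (last objective %.8f, change %.2e)",
      max_iter, F_cur, abs(diff(tail(trace_F, 2)))))
  }
  link_b <- drop(Xb %*% lam)
  log_z <- log_sum_exp(link_b)
  raw_b <- exp(link_b - log_z)
  H <- -sum(raw_b * log(pmax(raw_b, 1e-300)))
  structure(list(
    beta = setNames(lam, colnames(Xb)), penalties = beta,
    scaling = fe$scaling, info = fe$info, config = config,
    log_z = log_z, entropy = H, k = sum(lam != 0),
    n_presence = m, n_background = nrow(Xb),
    objective = trace_F, iterations = it, converged = converged),
    class = "maxent_fit")
}

#' @export
print.maxent_fit <- function(x, ...) {
  cat(sprintf(
    "<maxent_fit> %s features, RM = %g: %d presences vs %d background\n  k = %d nonzero of %d features; H = %.3f; converged in %d iterations\n",
    paste(x$config$feature_classes, collapse = ""), x$config$rm,
    x$n_presence, x$n_background, x$k, length(x$beta), x$entropy, x$iterations))
  invisible(x)
}

#' Predict from a fitted maximum-entropy model
#'
#' `link` is the linear predictor; `raw` is `exp(link - log Z)` and sums to
#' one over the training background; `cloglog` is the entropy transform
#' `1 - exp(-exp(H) * raw)`, a monotone suitability index in (0, 1).
#'
#' @param object a `maxent_fit`.
#' @param newdata data frame of raw predictor variables.
#' @param type `"cloglog"` (default), `"link"` or `"raw"`.
#' @param ... unused.
#' @export
predict.maxent_fit <- function(object, newdata,
                               type = c("cloglog", "link", "raw"), ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(names(object$scaling$min), names(newdata))
  if (length(miss)) stop("missing predictor variable(s): ", paste(miss, collapse = ", "))
  fe <- expand_features(newdata, object$config$feature_classes,
                        scaling = object$scaling,
                        hinge_knots = object$config$hinge_knots)
  link <- drop(fe$design %*% object$beta)
  switch(type,
         link = link,
         raw = exp(link - object$log_z),
         cloglog = 1 - exp(-exp(object$entropy) * exp(link - object$log_z)))
}

#' Project model predictions over a raster stack
#'
#' Evaluates the fitted model cellwise on a predictor stack at any scale
#' sharing the model's variables (e.g. the native 5 m stack after fitting at
#' the aggregated scale).
#'
#' @param model a `maxent_fit`.
#' @param stack a `pred_stack`.
#' @param type prediction scale, as in [predict.maxent_fit()].
#' @return a `crast` of predictions.
#' @export
predict_map <- function(model, stack, type = "cloglog") {
  df <- as_tibble.pred_stack(stack)
  vars <- names(model$scaling$min)
  keep <- complete.cases(df[vars])
  preds <- predict(model, df[keep, vars, drop = FALSE], type = type)
  ref <- stack$layers[[1]]
  v <- matrix(NA_real_, nrow(ref$v), ncol(ref$v))
  v[cbind(df$row[keep], df$col[keep])] <- preds
  crast(v, ref$cell_m, ref$xmin, ref$ymin)
}

#' @method tidy maxent_fit
#' @export
tidy.maxent_fit <- function(x, ...) {
  dplyr::mutate(x$info, estimate = unname(x$beta[x$info$column]),
                penalty = unname(x$penalties[x$info$column])) |>
    dplyr::rename(term = "column")
}

#' @method glance maxent_fit
#' @export
glance.maxent_fit <- function(x, ...) {
  tibble::tibble(n_presence = x$n_presence, n_background = x$n_background,
                 n_features = length(x$beta), k = x$k, entropy = x$entropy,
                 log_z = x$log_z, rm = x$config$rm,
                 classes = paste(x$config$feature_classes, collapse = ""),
                 iterations = x$iterations, converged = x$converged)
}

#' Partial (delta-link) response of one predictor
#'
#' Varies the focal predictor across its training range while holding every
#' other predictor at its training midpoint, and returns the change in the
#' linear predictor relative to the midpoint conditions -- the delta-link
#' response curve. `response_slope()` summarises its overall direction as
#' the link change from the low to the high end of the range.
#'
#' @param model a `maxent_fit`.
#' @param variable predictor name.
#' @param n curve resolution.
#' @return tibble: `value` (raw scale), `delta_link`.
#' @export
partial_response <- function(model, variable, n = 101) {
  sc <- model$scaling
  stopifnot(variable %in% names(sc$min))
  mids <- (sc$min + sc$max) / 2
  grid <- as.data.frame(as.list(mids))[rep(1, n), , drop = FALSE]
  grid[[variable]] <- seq(sc$min[[variable]], sc$max[[variable]],
                          length.out = n)
  ref <- as.data.frame(as.list(mids))
  link <- predict(model, grid, type = "link")
  link0 <- predict(model, ref, type = "link")
  tibble::tibble(value = grid[[variable]], delta_link = link - link0)
}

#' @rdname partial_response
#' @export
response_slope <- function(model, variable) {
  pr <- partial_response(model, variable)
  pr$delta_link[nrow(pr)] - pr$delta_link[1]
}

#' Spearman correlation pruning
#'
#' Greedy collinearity filter: while any unresolved pair of variables has
#' `|rho| >` the threshold, drop the unprotected member (for two unprotected
#' variables, the one with the larger mean `|rho|` against all others). Two
#' protected variables in an offending pair are both kept with a warning.
#'
#' @param X data frame of candidate variables.
#' @param threshold absolute Spearman correlation limit.
#' @param protected variables never dropped.
#' @return character vector of retained variable names.
#' @export
spearman_prune <- function(X, threshold = 0.7, protected = character()) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  keep <- names(X)
  repeat {
    cm <- suppressWarnings(cor(X[keep], method = "spearman"))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    off <- which(abs(cm) > threshold, arr.ind = TRUE)
    off <- off[off[, 1] < off[, 2], , drop = FALSE]
    if (nrow(off) == 0) break
    droppable <- apply(off, 1, function(ij) {
      pair <- keep[ij]
      !all(pair %in% protected)
    })
    if (!any(droppable)) {
      warning("offending pair(s) among protected variables kept: ",
              paste(unique(c(keep[off])), collapse = ", "))
      break
    }
    off <- off[droppable, , drop = FALSE]
    worst <- off[which.max(abs(cm[off])), ]
    pair <- keep[worst]
    cand <- setdiff(pair, protected)
    drop_var <- if (length(cand) == 1) cand else {
      mean_rho <- colMeans(abs(cm[, cand, drop = FALSE]))
      cand[which.max(mean_rho)]
    }
    keep <- setdiff(keep, drop_var)
    if (length(keep) < 2) break
  }
  keep
}

#' Iterative VIF pruning
#'
#' Repeatedly drops the unprotected variable with the largest variance
#' inflation factor (`1 / (1 - R^2)` from regressing it on the others) until
#' all VIFs are at most `max_vif`. Perfect collinearity within the protected
#' set is an error.
#'
#' @inheritParams spearman_prune
#' @param max_vif VIF ceiling.
#' @export
vif_prune <- function(X, max_vif = 5, protected = character()) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2)
  keep <- names(X)
  vif_of <- function(v, vars) {
    others <- setdiff(vars, v)
    r2 <- summary(lm(X[[v]] ~ ., data = X[others]))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  }
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(keep, vif_of, 0, vars = keep)
    if (max(vifs) <= max_vif) break
    cand <- setdiff(keep, protected)
    if (length(cand) == 0 || max(vifs[cand]) <= max_vif) {
      # only protected variables remain above the ceiling
      if (max(vifs) > 1e8) {
        stop("perfect collinearity among protected variables")
      }
      warning("VIF above the ceiling among protected variables kept: ",
              paste(keep[vifs > max_vif], collapse = ", "))
      break
    }
    keep <- setdiff(keep, cand[which.max(vifs[cand])])
  }
  keep
}

#' Accessible background mask
#'
#' Cells eligible as background: land, within `max_dist_m` of the shoreline,
#' and with no NoData in any predictor layer. Masks are nested in
#' `max_dist_m` by construction.
#'
#' @param stack a `pred_stack` containing `DIST_COAST_M`.
#' @param max_dist_m distance ceiling (m); `Inf` for all valid land.
#' @return a `crast` with 1 = accessible, NA elsewhere.
#' @export
accessible_mask <- function(stack, max_dist_m = 300) {
  stopifnot(inherits(stack, "pred_stack"),
            "DIST_COAST_M" %in% names(stack$layers))
  ok <- Reduce(`&`, lapply(stack$layers, function(l) !is.na(l$v)))
  ok <- ok & stack$layers$DIST_COAST_M$v <= max_dist_m
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) stop("accessible mask is empty")
  ref <- stack$layers[[1]]
  crast(ifelse(ok, 1, NA), ref$cell_m, ref$xmin, ref$ymin)
}

#' Realized background:presence ratio
#'
#' Reported to one decimal, the convention used for the design summary
#' (e.g. 744 background over 28 presences is 26.6:1).
#' @param n_background,n_presence sample sizes.
#' @export
realized_ratio <- function(n_background, n_presence) {
  stopifnot(n_presence >= 1)
  round(n_background / n_presence, 1)
}

#' Sample background cells from the accessible mask
#'
#' Simple random sampling without replacement of
#' `min(mask size, round(target_ratio * n_presence))` cells.
#'
#' @param mask accessibility `crast` from [accessible_mask()].
#' @param n_presence number of presences.
#' @param target_ratio target background:presence ratio.
#' @param seed integer seed.
#' @return tibble of cells (`row`, `col`, `x`, `y`) with attributes
#'   `realized_ratio` and `n_presence`.
#' @export
sample_background <- function(mask, n_presence, target_ratio = 25, seed = 42) {
  cells <- which(mask$v == 1)
  if (length(cells) < n_presence) {
    warning("accessible mask smaller than the number of presences")
  }
  n_bg <- min(length(cells), round(target_ratio * n_presence))
  sel <- withr::with_seed(seed, sample(cells, n_bg))
  out <- cr_coords(mask, row(mask$v)[sel], col(mask$v)[sel])
  attr(out, "realized_ratio") <- realized_ratio(n_bg, n_presence)
  attr(out, "n_presence") <- n_presence
  out
}

#' Corrected Akaike information criterion for a maxent fit
#'
#' `AICc = 2k - 2LL + 2k(k + 1) / (n - k - 1)` with `LL` the sum of log raw
#' probabilities at the presence rows and `k` the number of nonzero
#' coefficients; undefined (NA, with a message) when `n <= k + 1`.
#'
#' @param model a `maxent_fit`.
#' @param presence data frame of presence predictor rows.
#' @export
aicc <- function(model, presence) {
  n <- nrow(presence)
  k <- model$k
  if (n <= k + 1) {
    message("AICc undefined: n <= k + 1; model excluded from delta-AICc ranking")
    return(NA_real_)
  }
  ll <- sum(log(predict(model, presence, type = "raw")))
  2 * k - 2 * ll + 2 * k * (k + 1) / (n - k - 1)
}

#' Feature-class x regularization-multiplier selection grid
#'
#' For every class x RM combination, runs seeded k-fold cross-validation of
#' the presences (shared background), scores fold AUC, and summarises the
#' robustness score `mean AUC - 0.5 * SD`; delta-AICc comes from full-data
#' fits. The chosen configuration maximises robustness, with ties broken
#' toward the simpler feature class and then the larger RM.
#'
#' @param presence,background data frames of raw predictor variables.
#' @param classes_grid character vector of feature-class sets.
#' @param rm_grid numeric RM values.
#' @param folds number of CV folds.
#' @param seed integer seed for fold assignment.
#' @param hinge_knots knots for hinge classes.
#' @return list of class `model_selection`: `grid` tibble, `best` row,
#'   `best_fit` full-data model.
#' @export
select_model_grid <- function(presence, background,
                              classes_grid = c("l", "lq", "lqh"),
                              rm_grid = seq(1, 2, by = 0.2),
                              folds = 5, seed = 42, hinge_knots = 50) {
  stopifnot(length(classes_grid) >= 1, length(rm_grid) >= 1)
  n <- nrow(presence)
  if (folds > n) stop("more folds than presences")
  fold_id <- withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  rows <- list()
  fits <- list()
  for (cl in classes_grid) {
    for (rm in rm_grid) {
      cfg <- model_config(cl, rm = rm, hinge_knots = hinge_knots)
      aucs <- rep(NA_real_, folds)
      for (f in seq_len(folds)) {
        tr <- presence[fold_id != f, , drop = FALSE]
        te <- presence[fold_id == f, , drop = FALSE]
        if (nrow(tr) < 2 || nrow(te) < 1) next
        fit_f <- fit_maxent(tr, background, cfg)
        aucs[f] <- auc_mw(predict(fit_f, te, type = "cloglog"),
                          predict(fit_f, background, type = "cloglog"))
      }
      full <- fit_maxent(presence, background, cfg)
      fits[[paste(cl, rm)]] <- full
      mu <- mean(aucs, na.rm = TRUE); sdv <- sd(aucs, na.rm = TRUE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        classes = cl, rm = rm, auc_mean = mu, auc_sd = sdv,
        robustness = mu - 0.5 * sdv, k = full$k,
        aicc = aicc(full, presence))
    }
  }
  grid <- dplyr::bind_rows(rows) |>
    dplyr::mutate(delta_aicc = .data$aicc - min(.data$aicc, na.rm = TRUE))
  complexity <- match(grid$classes, c("l", "lq", "lqh", "qh", "h"))
  ord <- order(-grid$robustness, complexity, -grid$rm)
  best <- grid[ord[1], ]
  structure(list(grid = grid, best = best,
                 best_fit = fits[[paste(best$classes, best$rm)]],
                 fold_id = fold_id, seed = seed),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> chosen: %s, RM = %g (robustness %.4f)\n",
              x$best$classes, x$best$rm, x$best$robustness))
  print(x$grid, n = Inf)
  invisible(x)
}

#' @method tidy model_selection
#' @export
tidy.model_selection <- function(x, ...) x$grid

#' @method glance model_selection
#' @export
glance.model_selection <- function(x, ...) x$best

#' Serialize / restore a fitted model as JSON
#'
#' @param model a `maxent_fit`.
#' @param path JSON file path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(beta = as.list(model$beta),
              scaling = list(min = as.list(model$scaling$min),
                             max = as.list(model$scaling$max)),
              log_z = model$log_z, entropy = model$entropy, k = model$k,
              config = unclass(model$config),
              n_presence = model$n_presence, n_background = model$n_background)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
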