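#' Leave-one-cluster-out fold plan
#'
#' Presence points are clustered at `eps_m` (epsilon-graph components via
#' [consolidate_sites()], the minPts = 1 DBSCAN case) and each cluster forms
#' one holdout fold, so spatially proximate presences are never split across
#' training and test. The 250 m default aggregates detections into
#' ecological patches well above within-site spacing; 150-300 m are the
#' supported sensitivity values.
#'
#' @param presences tibble with `x`, `y` (one row per presence site).
#' @param eps_m clustering radius (m).
#' @return tibble `presences` plus `fold` column; error when everything
#'   falls in a single cluster.
#' @export
loco_folds <- function(presences, eps_m = 250) {
  out <- consolidate_sites(presences, eps_m = eps_m) |>
    dplyr::rename(fold = "site_cluster")
  if (length(unique(out$fold)) < 2) {
    stop("all presences fall in one cluster at eps_m = ", eps_m,
         "; use a smaller eps_m")
  }
  out
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Rank-based AUC with ties counted one half; identical to the trapezoidal
#' area under the empirical ROC.
#'
#' @param pos_scores,neg_scores score vectors for positives (presences) and
#'   negatives (background).
#' @export
auc_mw <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("both score sets must be nonempty")
  }
  r <- rank(c(pos_scores, neg_scores))
  m <- length(pos_scores); n <- length(neg_scores)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

# empirical ROC as step coordinates (fpr, tpr), from (0,0) to (1,1)
roc_points <- function(pos, neg) {
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  fpr <- vapply(th, function(t) mean(neg >= t), 0)
  tpr <- vapply(th, function(t) mean(pos >= t), 0)
  tibble::tibble(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Standardized partial AUC at high specificity
#'
#' Trapezoidal ROC area restricted to specificity in `spec_range`
#' (false-positive rate in `[0, 1 - spec_min]`, with vertical interpolation
#' at the boundary), then McClish-standardized:
#' `pAUC* = (1 + (A - A_min) / (A_max - A_min)) / 2`, where `A_max` is the
#' band width and `A_min` the chance (diagonal) area, so chance maps to 0.5
#' and perfection to 1.
#'
#' @inheritParams auc_mw
#' @param spec_range specificity band, default `c(0.90, 1)`.
#' @export
pauc_standardized <- function(pos_scores, neg_scores, spec_range = c(0.90, 1)) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("both score sets must be nonempty")
  }
  fmax <- 1 - spec_range[1]
  rp <- roc_points(pos_scores, neg_scores)
  # restrict to fpr <= fmax with linear interpolation at the boundary
  f <- rp$fpr; t <- rp$tpr
  keep <- f <= fmax + 1e-15
  fs <- f[keep]; ts <- t[keep]
  if (max(f) > fmax && max(fs) < fmax) {
    i <- which(f > fmax)[1]
    frac <- (fmax - f[i - 1]) / (f[i] - f[i - 1])
    fs <- c(fs, fmax); ts <- c(ts, t[i - 1] + frac * (t[i] - t[i - 1]))
  }
  A <- sum(diff(fs) * (head(ts, -1) + tail(ts, -1)) / 2)
  A_max <- fmax
  A_min <- fmax^2 / 2
  0.5 * (1 + (A - A_min) / (A_max - A_min))
}

#' Range-relative RMSE
#'
#' `sqrt(mean((score - label)^2))` normalized by the range of the predicted
#' scores within the fold; flagged `NaN` (and excluded from fold summaries)
#' when the score range is zero.
#'
#' @param scores predicted scores.
#' @param labels 0/1 labels aligned with `scores`.
#' @export
rel_rmse <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  rng <- max(scores) - min(scores)
  if (rng == 0) {
    warning("score range is zero; RelRMSE undefined")
    return(NaN)
  }
  sqrt(mean((scores - labels)^2)) / rng
}

#' Leave-one-cluster-out evaluation
#'
#' For each fold: fit on the remaining presence clusters plus the training
#' background, score the held-out presences against the fold's evaluation
#' background (the background sample minus any cell holding a test-fold
#' presence), and record AUC, standardized pAUC and RelRMSE. A failed fold
#' is flagged and the summary covers the remaining folds with a warning.
#'
#' @param presence_df data frame of presence predictor rows.
#' @param background_df data frame of background predictor rows.
#' @param folds integer fold id per presence row (see [loco_folds()]).
#' @param config a [model_config()].
#' @param bg_cells optional tibble (`row`, `col`) of background cells,
#'   aligned with `background_df`, used to exclude test-presence cells.
#' @param presence_cells optional tibble (`row`, `col`) per presence.
#' @return `validation_report`: per-fold tibble plus mean/SD summaries;
#'   labelled `"LOCO"`.
#' @export
evaluate_loco <- function(presence_df, background_df, folds,
                          config = model_config(), bg_cells = NULL,
                          presence_cells = NULL) {
  stopifnot(nrow(presence_df) == length(folds))
  ids <- sort(unique(folds))
  if (length(ids) < 2) stop("need at least two folds")
  rows <- list()
  for (f in ids) {
    tr <- presence_df[folds != f, , drop = FALSE]
    te <- presence_df[folds == f, , drop = FALSE]
    keep_bg <- rep(TRUE, nrow(background_df))
    if (!is.null(bg_cells) && !is.null(presence_cells)) {
      te_cells <- presence_cells[folds == f, , drop = FALSE]
      keep_bg <- !(paste(bg_cells$row, bg_cells$col) %in%
                     paste(te_cells$row, te_cells$col))
    }
    res <- tryCatch({
      fit <- fit_maxent(tr, background_df, config)
      ps <- predict(fit, te, type = "cloglog")
      bs <- predict(fit, background_df[keep_bg, , drop = FALSE], type = "cloglog")
      tibble::tibble(
        fold = f, n_test = nrow(te), n_eval_bg = sum(keep_bg),
        auc = auc_mw(ps, bs),
        pauc = pauc_standardized(ps, bs),
        rel_rmse = suppressWarnings(
          rel_rmse(c(ps, bs), c(rep(1, length(ps)), rep(0, length(bs))))),
        failed = FALSE)
    }, error = function(e) {
      warning(sprintf("fold %s failed: %s", f, conditionMessage(e)))
      tibble::tibble(fold = f, n_test = nrow(te), n_eval_bg = NA_integer_,
                     auc = NA_real_, pauc = NA_real_, rel_rmse = NA_real_,
                     failed = TRUE)
    })
    rows[[length(rows) + 1]] <- res
  }
  new_validation_report(dplyr::bind_rows(rows), label = "LOCO",
                        config = config)
}

#' Random k-fold cross-validation of presences
#'
#' Random (non-spatial) presence folds with shared background, used for the
#' selection grid and the mask/ratio sweeps. Reports carry the
#' `"random-CV"` label so they are never conflated with the spatial LOCO
#' estimates.
#'
#' @inheritParams evaluate_loco
#' @param k number of folds (2..n).
#' @param seed integer seed for fold assignment.
#' @export
kfold_cv <- function(presence_df, background_df, k = 5, seed = 42,
                     config = model_config()) {
  n <- nrow(presence_df)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("more folds than presences")
  fold_id <- withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  rep_ <- evaluate_loco(presence_df, background_df, fold_id, config)
  rep_$label <- "random-CV"
  rep_
}

new_validation_report <- function(per_fold, label, config, eps_m = NA_real_) {
  ok <- !per_fold$failed & is.finite(per_fold$auc)
  summ <- tibble::tibble(
    metric = c("auc", "pauc", "rel_rmse"),
    mean = c(mean(per_fold$auc[ok]), mean(per_fold$pauc[ok]),
             mean(per_fold$rel_rmse[ok & is.finite(per_fold$rel_rmse)])),
    sd = c(sd(per_fold$auc[ok]), sd(per_fold$pauc[ok]),
           sd(per_fold$rel_rmse[ok & is.finite(per_fold$rel_rmse)])))
  structure(list(per_fold = per_fold, summary = summ, label = label,
                 eps_m = eps_m, config = config),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> [%s] %d folds\n", x$label, nrow(x$per_fold)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' @method tidy validation_report
#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::mutate(x$per_fold, label = x$label)
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(label = x$label, n_folds = nrow(x$per_fold),
                 auc_mean = s$mean[s$metric == "auc"],
                 auc_sd = s$sd[s$metric == "auc"],
                 pauc_mean = s$mean[s$metric == "pauc"],
                 rel_rmse_mean = s$mean[s$metric == "rel_rmse"])
}

#' @method autoplot validation_report
#' @export
autoplot.validation_report <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_fold, c("auc", "pauc", "rel_rmse"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::labs(title = paste0("Per-fold metrics [", object$label, "]"),
                  x = NULL, y = NULL)
}
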