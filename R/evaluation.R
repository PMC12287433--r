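#' Well-grouped k-fold partition
#'
#' Partitions distinct wells into `k` folds of near-equal size (sizes
#' differ by at most 1) after a seeded shuffle. Grouping at the well
#' level ("cross-validation by dish") keeps all images of one well in the
#' same fold, so a classifier is never tested on images of a well it has
#' seen during training.
#'
#' @param well_ids Character/factor vector of well identifiers (may
#'   contain repeats; distinct values are partitioned).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A list of `k` disjoint character vectors covering all wells.
#' @examples
#' folds <- grouped_kfold(sprintf("W%02d", 1:34), k = 4, seed = 1)
#' lengths(folds)  # 9 9 8 8
#' @export
grouped_kfold <- function(well_ids, k, seed = 1L) {
  check_count(k, "k")
  if (k < 2) stopf("`k` must be at least 2")
  wells <- unique(as.character(well_ids))
  if (length(wells) < k)
    stopf("cannot make %d folds from %d distinct wells", k, length(wells))
  local_seed(seed, {
    shuffled <- sample(wells)
    unname(split(shuffled, rep(seq_len(k), length.out = length(shuffled))))
  })
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the AUC equals the
#' probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted one half. Midranks make the
#' rank-sum form exactly equal to brute-force pairwise concordance.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stopf("`scores` and `labels` must have equal length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stopf("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated well-grouped cross-validation
#'
#' The evaluation protocol for one (task, day) cell: in each of
#' `n_repeats` repeats the wells are re-partitioned into `n_folds`
#' well-grouped folds with a fresh derived seed; for every fold the full
#' pipeline (constant filter, PCA + PLS-DA reduction, random forest) is
#' fitted on the training wells' images only and the held-out wells'
#' images are scored; the fold AUCs are averaged into that repeat's
#' "average AUC". The distribution of the `n_repeats` averages is the
#' quantity summarized per day.
#'
#' A fold whose held-out images are single-class has no defined AUC; it
#' is recorded as `NA` with a warning and excluded from that repeat's
#' mean.
#'
#' @param features Feature table from [batch_extract()] (must contain
#'   `well_id`, optionally `day`, and the `shell_*` columns).
#' @param outcomes Outcome table with `well_id` and `myf5_pct`.
#' @param task A [task_spec()].
#' @param day Restrict to images of this acquisition day (`NULL` uses all
#'   rows of `features`).
#' @param n_folds Folds per repeat, default 4.
#' @param n_repeats Repeats, default 50.
#' @param seed Integer seed; every repeat and fold derives its own
#'   sub-seed.
#' @param n_pc,ntree,mtry,scale Pipeline hyperparameters, see
#'   [train_efficiency_model()].
#' @return Object of class `"cv_result"`: `folds` (data.frame of repeat,
#'   fold, AUC and set sizes), `avg_auc` (numeric, one average per
#'   repeat), plus the call parameters.
#' @examples
#' \donttest{
#' cfg <- plate_config(n_wells = 8, acquisition_days = 38,
#'                     positions_per_well = 3,
#'                     image_height = 64, image_width = 64)
#' ds <- generate_dataset(cfg)
#' fx <- batch_extract(ds)
#' cv <- repeated_cv(fx, ds$outcomes, task_spec(2), day = 38,
#'                   n_repeats = 2, seed = 1)
#' cv$avg_auc
#' }
#' @export
repeated_cv <- function(features, outcomes, task, day = NULL,
                        n_folds = 4, n_repeats = 50, seed = 1L,
                        n_pc = 10, ntree = 100, mtry = NULL, scale = FALSE) {
  stopifnot(inherits(task, "task_spec"))
  check_count(n_folds, "n_folds")
  check_count(n_repeats, "n_repeats")
  if (!is.null(day)) {
    if (!"day" %in% names(features)) stopf("`features` has no `day` column")
    features <- features[features$day == day, , drop = FALSE]
    if (nrow(features) == 0) stopf("no feature rows for day %s", format(day))
  }
  shells <- shell_columns(features)
  if (length(shells) == 0) stopf("`features` contains no shell_* columns")
  x <- as.matrix(features[, shells, drop = FALSE])
  y <- assign_labels(outcomes, features, task)
  wells <- features$well_id
  well_labels <- tapply(y, wells, function(v) v[1])
  if (length(unique(well_labels)) < 2)
    stopf("all wells fall in one class for this task/day; nothing to evaluate")
  res <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- grouped_kfold(wells, n_folds, seed = derive_seed(seed, "fold", r))
    auc <- rep(NA_real_, n_folds)
    n_train <- n_test <- integer(n_folds)
    for (f in seq_len(n_folds)) {
      test_idx <- wells %in% folds[[f]]
      n_train[f] <- sum(!test_idx); n_test[f] <- sum(test_idx)
      if (length(unique(y[!test_idx])) < 2) {
        warning(sprintf("repeat %d fold %d: single-class training set, AUC skipped",
                        r, f), call. = FALSE)
        next
      }
      if (length(unique(y[test_idx])) < 2) {
        warning(sprintf("repeat %d fold %d: single-class test set, AUC undefined",
                        r, f), call. = FALSE)
        next
      }
      model <- train_efficiency_model(x[!test_idx, , drop = FALSE], y[!test_idx],
                                      n_pc = n_pc, scale = scale, ntree = ntree,
                                      mtry = mtry,
                                      seed = derive_seed(seed, "rf", r, f))
      auc[f] <- roc_auc(predict(model, x[test_idx, , drop = FALSE]), y[test_idx])
    }
    res[[r]] <- data.frame(repeat_id = r, fold = seq_len(n_folds), auc = auc,
                           n_train = n_train, n_test = n_test)
  }
  folds_df <- do.call(rbind, res)
  avg <- tapply(folds_df$auc, folds_df$repeat_id, mean, na.rm = TRUE)
  structure(list(folds = folds_df,
                 avg_auc = as.numeric(avg),
                 task = task, day = day,
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: task %d%s, %d x %d-fold well-grouped CV>\n",
              x$task$task_id,
              if (!is.null(x$day)) sprintf(", day %d", x$day) else "",
              x$n_repeats, x$n_folds))
  cat(sprintf("  average AUC: median %.3f, IQR [%.3f, %.3f]\n",
              stats::median(x$avg_auc),
              stats::quantile(x$avg_auc, 0.25),
              stats::quantile(x$avg_auc, 0.75)))
  invisible(x)
}

#' Manufacturing-filter metrics from confusion counts
#'
#' Evaluates a classifier used as a production filter. Under Task-1
#' semantics (exclusion filter) the predicted positives — images flagged
#' as low-efficiency "defects" — are removed and the retained pool is
#' what moves on; impurity is the proportion of true defects, before
#' filtering versus among the retained images, and the FPR is the
#' fraction of non-defective images wrongly flagged. Under Task-2
#' semantics (retention filter) the predicted positives are kept;
#' impurity tracks the proportion of true high-quality images before
#' versus among the retained, and the FNR is the fraction of truly
#' high-quality images wrongly discarded. Impurity Change is the ratio
#' after/before: below 1 means defects were depleted (Task 1), above 1
#' means the desired class was enriched (Task 2).
#'
#' The significance of the composition change is a two-sided Fisher exact
#' test on the 2 x 2 table (positive/negative x before-pool/after-pool);
#' a two-proportion test is available via `p_method = "prop"`.
#'
#' `filter_report_counts()` takes the four counts directly;
#' `filter_report()` derives them from per-image true and predicted
#' labels.
#'
#' @param n_total Images before filtering.
#' @param n_positive_before True positives (for the task) before
#'   filtering.
#' @param n_flagged Images predicted positive by the model.
#' @param n_positive_after True positives among the retained pool
#'   (Task 1: not flagged; Task 2: flagged).
#' @param task A [task_spec()].
#' @param p_method `"fisher"` (default) or `"prop"`.
#' @return Object of class `"filter_report"` with the counts, the rates
#'   (`fpr`, `fnr`), `impurity_before`, `impurity_after`,
#'   `impurity_change`, the percent change in the positive-class rate
#'   (`rate_change_pct`; a reduction for Task 1, an enrichment for
#'   Task 2), and `p_value`.
#' @examples
#' # an exclusion filter that removes 196 of 714 images
#' filter_report_counts(714, 147, 196, 60, task_spec(1))
#' @export
filter_report_counts <- function(n_total, n_positive_before, n_flagged,
                                 n_positive_after, task,
                                 p_method = c("fisher", "prop")) {
  stopifnot(inherits(task, "task_spec"))
  p_method <- match.arg(p_method)
  counts <- c(n_total, n_positive_before, n_flagged, n_positive_after)
  if (any(counts < 0) || any(counts != floor(counts)))
    stopf("counts must be non-negative integers")
  if (n_positive_before > n_total || n_flagged > n_total)
    stopf("inconsistent counts: subsets exceed the total")
  exclusion <- task$task_id == 1
  n_retained <- if (exclusion) n_total - n_flagged else n_flagged
  if (n_positive_after > n_retained)
    stopf("inconsistent counts: more positives after than retained images")
  n_negative_before <- n_total - n_positive_before
  if (exclusion) {
    pos_flagged <- n_positive_before - n_positive_after
    neg_flagged <- n_flagged - pos_flagged
    fpr <- if (n_negative_before > 0) neg_flagged / n_negative_before else NA_real_
    fnr <- if (n_positive_before > 0) n_positive_after / n_positive_before else NA_real_
  } else {
    pos_missed <- n_positive_before - n_positive_after
    fnr <- if (n_positive_before > 0) pos_missed / n_positive_before else NA_real_
    fpr <- if (n_negative_before > 0)
      (n_retained - n_positive_after) / n_negative_before else NA_real_
  }
  impurity_before <- n_positive_before / n_total
  impurity_after <- if (n_retained > 0) n_positive_after / n_retained else NA_real_
  impurity_change <- impurity_after / impurity_before
  rate_change_pct <- if (exclusion) (1 - impurity_change) * 100
                     else (impurity_change - 1) * 100
  p_value <- if (n_retained > 0) {
    tab <- matrix(c(n_positive_before, n_negative_before,
                    n_positive_after, n_retained - n_positive_after), nrow = 2)
    if (p_method == "fisher") stats::fisher.test(tab)$p.value
    else stats::prop.test(c(n_positive_before, n_positive_after),
                          c(n_total, n_retained))$p.value
  } else NA_real_
  structure(list(task = task,
                 n_total = n_total,
                 n_positive_before = n_positive_before,
                 n_flagged = n_flagged,
                 n_retained = n_retained,
                 n_positive_after = n_positive_after,
                 fpr = fpr, fnr = fnr,
                 impurity_before = impurity_before,
                 impurity_after = impurity_after,
                 impurity_change = impurity_change,
                 rate_change_pct = rate_change_pct,
                 p_value = p_value, p_method = p_method),
            class = "filter_report")
}

#' @rdname filter_report_counts
#' @param labels_true,labels_pred Equal-length 0/1 vectors of true task
#'   labels and model predictions.
#' @export
filter_report <- function(labels_true, labels_pred, task,
                          p_method = c("fisher", "prop")) {
  stopifnot(inherits(task, "task_spec"))
  labels_true <- as.integer(labels_true)
  labels_pred <- as.integer(labels_pred)
  if (length(labels_true) != length(labels_pred))
    stopf("`labels_true` and `labels_pred` must have equal length")
  retained <- if (task$task_id == 1) labels_pred == 0 else labels_pred == 1
  filter_report_counts(n_total = length(labels_true),
                       n_positive_before = sum(labels_true == 1),
                       n_flagged = sum(labels_pred == 1),
                       n_positive_after = sum(labels_true == 1 & retained),
                       task = task, p_method = p_method)
}

#' @export
print.filter_report <- function(x, digits = 3, ...) {
  mode <- if (x$task$task_id == 1) "exclusion" else "retention"
  cat(sprintf("Filter report (Task %d, %s filter)\n", x$task$task_id, mode))
  cat(sprintf("  images: %d total, %d flagged positive, %d retained\n",
              x$n_total, x$n_flagged, x$n_retained))
  cat(sprintf("  positives: %d (%.1f%%) before -> %d (%.1f%%) among retained\n",
              x$n_positive_before, 100 * x$impurity_before,
              x$n_positive_after, 100 * x$impurity_after))
  cat(sprintf("  impurity change %.3f (%s %.1f%%), FPR %.3f, FNR %.3f, p = %.3g\n",
              x$impurity_change,
              if (x$task$task_id == 1) "defect-rate reduction" else "enrichment",
              x$rate_change_pct, x$fpr, x$fnr, x$p_value))
  invisible(x)
}

#' Pooled out-of-fold filter evaluation
#'
#' Runs one seeded well-grouped k-fold pass over the images of a day:
#' each fold's held-out images are scored by a pipeline fitted on the
#' other folds, giving exactly one leakage-free prediction per image.
#' The pooled predictions are thresholded and summarized as a
#' [filter_report()].
#'
#' @inheritParams repeated_cv
#' @param threshold Decision threshold passed to [classify()].
#' @inheritParams filter_report_counts
#' @return A `"filter_report"` with attributes `scores` and `labels`
#'   (the pooled out-of-fold scores and true labels).
#' @export
oof_filter_report <- function(features, outcomes, task, day = NULL,
                              n_folds = 4, seed = 1L, threshold = 0.5,
                              n_pc = 10, ntree = 100, mtry = NULL,
                              scale = FALSE, p_method = c("fisher", "prop")) {
  stopifnot(inherits(task, "task_spec"))
  if (!is.null(day)) features <- features[features$day == day, , drop = FALSE]
  if (nrow(features) == 0) stopf("no feature rows to evaluate")
  shells <- shell_columns(features)
  x <- as.matrix(features[, shells, drop = FALSE])
  y <- assign_labels(outcomes, features, task)
  wells <- features$well_id
  folds <- grouped_kfold(wells, n_folds, seed = derive_seed(seed, "oof"))
  scores <- rep(NA_real_, nrow(features))
  for (f in seq_along(folds)) {
    test_idx <- wells %in% folds[[f]]
    if (length(unique(y[!test_idx])) < 2)
      stopf("fold %d has a single-class training set; use more wells", f)
    model <- train_efficiency_model(x[!test_idx, , drop = FALSE], y[!test_idx],
                                    n_pc = n_pc, scale = scale, ntree = ntree,
                                    mtry = mtry,
                                    seed = derive_seed(seed, "oof-rf", f))
    scores[test_idx] <- predict(model, x[test_idx, , drop = FALSE])
  }
  pred <- classify(scores, threshold)
  rep_out <- filter_report(y, pred, task, p_method = p_method)
  attr(rep_out, "scores") <- scores
  attr(rep_out, "labels") <- y
  rep_out
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test between two samples: exact enumeration when
#' both samples have at most 10 observations and no ties are present,
#' otherwise the normal approximation with continuity and tie
#' correction. The U statistic counts pairs where the first sample
#' exceeds the second (ties half-weighted).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`); default
#'   `NULL` chooses by the size/tie rule above.
#' @return List with `U` and `p.value`.
#' @examples
#' mannwhitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannwhitney_u <- function(sample_a, sample_b, exact = NULL) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stopf("both samples must be non-empty")
  has_ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  if (is.null(exact))
    exact <- length(sample_a) <= 10 && length(sample_b) <= 10 && !has_ties
  res <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  list(U = unname(res$statistic), p.value = res$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, clipped to 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pairwise day comparison of cross-validation performance
#'
#' Compares the average-AUC distributions of several acquisition days
#' with all pairwise two-sided Mann-Whitney tests, Benjamini-Hochberg
#' adjusted across the pairs. A day is flagged best when its median
#' average AUC exceeds every other day's and all its pairwise q-values
#' fall below `alpha`.
#'
#' @param cv_results Named list of [repeated_cv()] results (or plain
#'   numeric vectors of average AUCs), one element per day.
#' @param alpha Significance level for the best-day flag, default 0.05.
#' @return Object of class `"day_comparison"`: `table` (data.frame of
#'   `day_a`, `day_b`, `U`, `p`, `q`), `medians`, and `best_day`
#'   (`NA` when no day qualifies).
#' @examples
#' x <- list(d14 = runif(20, 0.4, 0.6), d34 = runif(20, 0.8, 0.9))
#' compare_days(x)$best_day
#' @export
compare_days <- function(cv_results, alpha = 0.05) {
  if (length(cv_results) < 2)
    stopf("need distributions for at least 2 days")
  if (is.null(names(cv_results)) || any(names(cv_results) == ""))
    stopf("`cv_results` must be a named list (one name per day)")
  dists <- lapply(cv_results, function(v) {
    if (inherits(v, "cv_result")) v$avg_auc else as.numeric(v)
  })
  if (any(vapply(dists, length, integer(1)) == 0))
    stopf("every day needs a non-empty average-AUC distribution")
  days <- names(dists)
  pairs <- utils::combn(days, 2)
  tab <- data.frame(day_a = pairs[1, ], day_b = pairs[2, ],
                    U = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    mw <- mannwhitney_u(dists[[pairs[1, i]]], dists[[pairs[2, i]]])
    tab$U[i] <- mw$U
    tab$p[i] <- mw$p.value
  }
  tab$q <- bh_adjust(tab$p)
  med <- vapply(dists, stats::median, numeric(1))
  best <- NA_character_
  top <- names(which.max(med))
  if (sum(med == max(med)) == 1) {
    qs <- tab$q[tab$day_a == top | tab$day_b == top]
    if (all(qs < alpha)) best <- top
  }
  structure(list(table = tab, medians = med, best_day = best, alpha = alpha),
            class = "day_comparison")
}

#' @export
print.day_comparison <- function(x, ...) {
  cat(sprintf("Pairwise day comparison (%d pairs, BH-adjusted)\n",
              nrow(x$table)))
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("best day: %s (alpha = %g)\n",
              if (is.na(x$best_day)) "none" else x$best_day, x$alpha))
  invisible(x)
}

#' Test for no correlation
#'
#' Product-moment correlation with the t-distribution test of the null
#' of zero correlation.
#'
#' @param x,y Finite numeric vectors of equal length, n >= 3, each with
#'   positive variance.
#' @return List with `r` and `p.value`.
#' @examples
#' no_correlation_test(1:4, c(2, 1, 4, 3))$r  # 0.6
#' @export
no_correlation_test <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("zero variance in input; correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p.value = ct$p.value)
}
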