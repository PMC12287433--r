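test_that("grouped k-fold partitions wells evenly and deterministically", {
  wells <- sprintf("W%02d", 1:34)
  folds <- grouped_kfold(wells, 4, seed = 1)
  expect_equal(sort(lengths(folds), decreasing = TRUE), c(9, 9, 8, 8))
  expect_setequal(unlist(folds), wells)
  expect_equal(sum(lengths(folds)), 34)  # disjoint cover
  expect_identical(grouped_kfold(wells, 4, seed = 1), folds)
  distinct <- unique(lapply(1:20, function(s)
    grouped_kfold(wells, 4, seed = s)))
  expect_gt(length(distinct), 15)
  expect_error(grouped_kfold(wells[1:3], 4), "cannot make")
})

test_that("roc_auc equals brute-force pairwise concordance", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(1:6, c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(roc_auc(6:1, c(0, 0, 0, 1, 1, 1)), 0.0)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4)), 0.5)

  withr::with_seed(61, {
    for (i in 1:1000) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # inject ties
      expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
  # independent library cross-check
  withr::with_seed(62, {
    s <- runif(40); l <- rbinom(40, 1, 0.5)
  })
  proc_auc <- as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                             direction = "<")))
  expect_equal(roc_auc(s, l), proc_auc, tolerance = 1e-12)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("repeated grouped CV is reproducible, grouped, and skips undefined folds", {
  toy <- toy_feature_table(n_wells = 16, per_well = 4, shift = 2, seed = 71)
  cv1 <- suppressWarnings(
    repeated_cv(toy$features, toy$outcomes, task_spec(2), day = 38,
                n_folds = 4, n_repeats = 2, seed = 5, n_pc = 5, ntree = 50))
  cv2 <- suppressWarnings(
    repeated_cv(toy$features, toy$outcomes, task_spec(2), day = 38,
                n_folds = 4, n_repeats = 2, seed = 5, n_pc = 5, ntree = 50))
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$avg_auc, cv2$avg_auc)
  expect_length(cv1$avg_auc, 2)
  expect_true(all(cv1$folds$auc >= 0 & cv1$folds$auc <= 1, na.rm = TRUE))
  # well grouping: every fold's test size is a whole number of wells
  expect_true(all(cv1$folds$n_test %% 4 == 0))
  expect_true(all(cv1$folds$n_test + cv1$folds$n_train == 64))
  # a clear class signal is recovered out of fold
  expect_gt(mean(cv1$avg_auc), 0.9)

  # one positive well among eight: every fold is single-class somewhere
  lone <- toy_feature_table(n_wells = 8, per_well = 3, shift = 2, seed = 72)
  lone$outcomes$myf5_pct <- c(25, rep(5, 7))
  w <- testthat::capture_warnings(
    cvl <- repeated_cv(lone$features, lone$outcomes, task_spec(2), day = 38,
                       n_folds = 4, n_repeats = 1, seed = 1, n_pc = 5,
                       ntree = 30))
  expect_true(any(grepl("single-class", w)))
  expect_true(all(is.na(cvl$folds$auc)))
})

test_that("filter metrics reproduce worked confusion arithmetic", {
  # exclusion filter: 714 images, 147 true defects, 196 flagged, 60 remain
  fr1 <- filter_report_counts(714, 147, 196, 60, task_spec(1))
  expect_equal(round(100 * fr1$impurity_before, 1), 20.6)
  expect_equal(round(100 * fr1$impurity_after, 1), 11.6)
  expect_equal(round(fr1$impurity_change, 3), 0.563)
  expect_equal(round(fr1$fpr, 2), 0.19)
  expect_equal(fr1$fpr, 109 / 567, tolerance = 1e-12)
  expect_equal(fr1$n_retained, 518)
  # conservation: positives before = positives flagged + positives after
  expect_equal(fr1$n_positive_before - fr1$n_positive_after,
               147 - 60)
  expect_lt(fr1$p_value, 1e-4)

  # retention filter: 714 images, 189 high-quality, 383 kept, 174 of them good
  fr2 <- filter_report_counts(714, 189, 383, 174, task_spec(2))
  expect_equal(fr2$fnr, 15 / 189, tolerance = 1e-12)
  expect_equal(fr2$impurity_change, (174 / 383) / (189 / 714),
               tolerance = 1e-12)
  expect_equal(round(fr2$rate_change_pct), 72)

  # label-vector route agrees with the count route
  truth <- c(rep(1, 10), rep(0, 30))
  pred <- c(rep(1, 7), rep(0, 3), rep(1, 5), rep(0, 25))
  fr3 <- filter_report(truth, pred, task_spec(1))
  fr4 <- filter_report_counts(40, 10, 12, 3, task_spec(1))
  expect_equal(fr3[c("fpr", "fnr", "impurity_change")],
               fr4[c("fpr", "fnr", "impurity_change")])

  # identity filter: nothing excluded, impurity unchanged
  fr5 <- filter_report(truth, rep(0, 40), task_spec(1))
  expect_equal(fr5$impurity_change, 1.0)
  # empty retained pool is reported as undefined, not an error
  fr6 <- filter_report(truth, rep(1, 40), task_spec(1))
  expect_true(is.na(fr6$impurity_after))
  expect_error(filter_report(truth, pred[1:5], task_spec(1)), "equal length")
})

test_that("Mann-Whitney U handles exact, tied and separated cases", {
  mw <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1, tolerance = 1e-12)
  expect_equal(mannwhitney_u(c(1, 2), c(1, 2))$p.value, 1.0)
  expect_equal(mannwhitney_u(c(1, 2), c(3, 4))$U, 0)
  expect_error(mannwhitney_u(numeric(0), 1:3), "non-empty")

  # exact p agrees with direct enumeration of rank arrangements
  a <- c(0.3, 1.9, 2.2, 4.1); b <- c(0.9, 2.8, 3.3)
  u_of <- function(x, y) sum(outer(x, y, ">"))
  u_obs <- u_of(a, b)
  pooled <- c(a, b)
  combos <- utils::combn(7, 4)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mu <- length(a) * length(b) / 2
  p_exact <- mean(abs(us - mu) >= abs(u_obs - mu))
  expect_equal(mannwhitney_u(a, b)$p.value, p_exact, tolerance = 1e-12)
})

test_that("BH adjustment equals hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  withr::with_seed(81, p <- runif(25)^2)
  q <- bh_adjust(p)
  expect_true(all(q >= p & q <= 1))
  ord <- order(p)
  expect_true(all(diff(q[ord]) >= -1e-15))       # monotone step-up
  # a fully tied adjusted vector is a fixed point of the step-up
  expect_equal(bh_adjust(c(0.03, 0.03, 0.03)), c(0.03, 0.03, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("day comparison flags a clearly better day only", {
  withr::with_seed(91, {
    same <- list(d14 = runif(50, 0.45, 0.55), d17 = runif(50, 0.45, 0.55))
  })
  dc_same <- compare_days(same)
  expect_true(is.na(dc_same$best_day))
  expect_gt(min(dc_same$table$q), 0.05)

  withr::with_seed(92, {
    shifted <- list(d14 = runif(50, 0.4, 0.6), d24 = runif(50, 0.4, 0.6),
                    d34 = runif(50, 0.4, 0.6) + 0.3)
  })
  dc <- compare_days(shifted)
  expect_equal(dc$best_day, "d34")
  q34 <- dc$table$q[dc$table$day_a == "d34" | dc$table$day_b == "d34"]
  expect_true(all(q34 < 0.001))

  eight <- setNames(lapply(1:8, function(i) runif(10)),
                    sprintf("d%d", 1:8))
  expect_equal(nrow(compare_days(eight)$table), 28)  # choose(8, 2)
  expect_error(compare_days(shifted[1]), "at least 2")
})

test_that("null synthetic plates keep day-level performance at chance", {
  # With no class-to-feature link, every day's average-AUC distribution
  # should sit near 0.5. (The pairwise day q-values themselves are known
  # to be anticonservative under the null because the repeats of one day
  # re-use the same images and are not independent draws; see the
  # methods vignette.)
  medians <- numeric(20)
  for (s in 1:20) {
    toy <- toy_feature_table(n_wells = 20, per_well = 5, shift = 0,
                             seed = 300 + s)
    cv <- suppressWarnings(
      repeated_cv(toy$features, toy$outcomes, task_spec(2), day = 38,
                  n_folds = 4, n_repeats = 5, seed = s, n_pc = 5,
                  ntree = 30))
    medians[s] <- median(cv$avg_auc)
  }
  expect_true(all(abs(medians - 0.5) < 0.2))
  expect_lt(abs(mean(medians) - 0.5), 0.06)
})

test_that("no-correlation test matches closed forms and is calibrated", {
  expect_equal(no_correlation_test(1:10, 2 * (1:10))$r, 1)
  expect_equal(no_correlation_test(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6)
  n_hits <- 0
  for (i in 1:100) {
    withr::with_seed(2000 + i, {
      x <- rnorm(36); y <- rnorm(36)
    })
    if (no_correlation_test(x, y)$p.value < 0.05) n_hits <- n_hits + 1
  }
  expect_gte(n_hits, 1)
  expect_lte(n_hits, 10)
  expect_error(no_correlation_test(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(no_correlation_test(1:2, 1:2), "at least 3")
})
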