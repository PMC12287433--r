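#' Binary classification tasks on the efficiency score
#'
#' The two manufacturing-relevant tasks defined on the per-well MYF5+%
#' outcome: Task 1 flags low-efficiency wells (positive when the score is
#' strictly below 10, the "defective" wells a filter should remove), and
#' Task 2 flags high-efficiency wells (positive when the score is
#' strictly above 20, the wells a filter should retain). Both
#' inequalities are strict, so boundary scores (exactly 10 or 20) are
#' negative.
#'
#' @param task_id 1 or 2.
#' @return A list of class `"task_spec"` with `task_id`, `threshold` and
#'   `polarity` (`"below"` or `"above"`).
#' @examples
#' task_spec(1)
#' @export
task_spec <- function(task_id) {
  if (!task_id %in% c(1, 2)) stopf("`task_id` must be 1 or 2")
  structure(list(task_id = as.integer(task_id),
                 threshold = if (task_id == 1) 10 else 20,
                 polarity = if (task_id == 1) "below" else "above"),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("Task %d: positive when MYF5+%% %s %g\n", x$task_id,
              if (x$polarity == "below") "<" else ">", x$threshold))
  invisible(x)
}

# 0/1 label of an efficiency score under a task.
task_label <- function(task, myf5_pct) {
  stopifnot(inherits(task, "task_spec"))
  if (task$polarity == "below") as.integer(myf5_pct < task$threshold)
  else as.integer(myf5_pct > task$threshold)
}

#' Label images by the outcome of their well
#'
#' Every image inherits the binary task label of the well it was taken
#' from: all 21 positions of a well share one label because the outcome
#' (MYF5+% at the end of differentiation) is measured per well.
#'
#' @param outcomes Outcome table with `well_id` and `myf5_pct`.
#' @param images A metadata data.frame with a `well_id` column (e.g. the
#'   `metadata` of [generate_dataset()] or a [batch_extract()] table).
#' @param task A [task_spec()].
#' @return Integer vector of 0/1 labels, one per image row.
#' @examples
#' out <- data.frame(well_id = c("a", "b"), myf5_pct = c(5, 25))
#' imgs <- data.frame(well_id = c("a", "a", "b"))
#' assign_labels(out, imgs, task_spec(2))
#' @export
assign_labels <- function(outcomes, images, task) {
  stopifnot(inherits(task, "task_spec"))
  idx <- match(images$well_id, outcomes$well_id)
  if (anyNA(idx))
    stopf("unresolvable well_id(s): %s",
          paste(unique(images$well_id[is.na(idx)]), collapse = ", "))
  task_label(task, outcomes$myf5_pct[idx])
}

#' Drop zero-variance feature columns
#'
#' Removes columns that are constant on the supplied rows and records the
#' retained-column mask so exactly the same columns can be dropped from
#' unseen rows later (regardless of their variance there), keeping the
#' train/test contract leak-free.
#'
#' @param x Numeric matrix or data.frame of features (>= 2 rows).
#' @return List with `x` (reduced matrix) and `keep` (logical mask over
#'   the original columns).
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
#' remove_constant_columns(m)$keep
#' @export
remove_constant_columns <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stopf("need at least 2 rows to identify constant columns")
  rng <- apply(x, 2, function(col) diff(range(col)))
  keep <- is.finite(rng) & rng > 0
  if (!any(keep)) stopf("all feature columns are constant; nothing to fit")
  list(x = x[, keep, drop = FALSE], keep = keep)
}

#' Fit the reduced 11-column design (10 PCs + 1 PLS-DA component)
#'
#' Dimension reduction used upstream of the random forest: constant
#' columns are dropped, features are centered (optionally unit-scaled),
#' the first `n_pc` principal axes are fitted, and a single PLS-DA
#' discriminant axis is fitted on the principal-component scores against
#' the binary labels. The design matrix concatenates the `n_pc` PC scores
#' with the one discriminant score (11 columns by default). Every
#' statistic (mask, centers, axes) is estimated from the training rows
#' only; apply the fitted transform to new rows with `predict()`.
#'
#' With two classes and one component, PLS-DA reduces to the closed form
#' `w = S'(y - mean(y)) / ||S'(y - mean(y))||` on the centered score
#' matrix `S`, the direction maximizing covariance between the projected
#' scores and the labels.
#'
#' If the training features have rank below `n_pc`, the missing axes are
#' kept as all-zero columns and counted in `degenerate_axes`, so the
#' design always has `n_pc + 1` columns.
#'
#' @param x Feature matrix or data.frame (training rows).
#' @param y Binary 0/1 labels, both classes present.
#' @param n_pc Number of principal components, default 10.
#' @param scale Unit-variance scaling before PCA (default `FALSE`:
#'   shell features already share a normalized scale).
#' @return Object of class `"reduced_design"` with the fitted transform
#'   state and `design` (the training design matrix).
#' @examples
#' x <- matrix(rnorm(40 * 20), 40)
#' y <- rep(0:1, each = 20)
#' rd <- fit_reduced_design(x, y, n_pc = 5)
#' dim(rd$design)  # 40 x 6
#' @export
fit_reduced_design <- function(x, y, n_pc = 10, scale = FALSE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  check_count(n_pc, "n_pc")
  if (length(y) != nrow(x)) stopf("`y` must have one label per row of `x`")
  if (length(unique(y)) < 2)
    stopf("training labels contain a single class; cannot fit a discriminant")
  if (nrow(x) < n_pc + 2)
    stopf("need at least %d training rows for %d components, got %d",
          n_pc + 2, n_pc, nrow(x))
  cf <- remove_constant_columns(x)
  if (ncol(cf$x) < n_pc)
    stopf(paste("only %d non-constant feature columns for %d requested",
                "principal components; lower `n_pc`"),
          ncol(cf$x), n_pc)
  pr <- stats::prcomp(cf$x, center = TRUE, scale. = scale, rank. = n_pc)
  rot <- pr$rotation
  n_avail <- ncol(rot)
  degenerate <- 0L
  # axes beyond numerical rank carry ~zero variance; treat them as absent
  tol <- pr$sdev[1] * 1e-8
  real <- which(pr$sdev[seq_len(n_avail)] > tol)
  if (length(real) < n_pc) {
    keep_axes <- seq_len(length(real))
    rot <- cbind(rot[, keep_axes, drop = FALSE],
                 matrix(0, nrow(rot), n_pc - length(real)))
    degenerate <- n_pc - length(real)
  } else if (n_avail < n_pc) {
    rot <- cbind(rot, matrix(0, nrow(rot), n_pc - n_avail))
    degenerate <- n_pc - n_avail
  }
  colnames(rot) <- sprintf("PC%d", seq_len(n_pc))
  obj <- structure(list(keep = cf$keep,
                        center = pr$center,
                        scale = pr$scale,
                        rotation = rot,
                        pls_weight = NULL,
                        n_pc = as.integer(n_pc),
                        degenerate_axes = degenerate,
                        sdev = pr$sdev),
                   class = "reduced_design")
  scores <- pc_scores(obj, x)
  w <- crossprod(scores, y - mean(y))
  nw <- sqrt(sum(w^2))
  obj$pls_weight <- if (nw > 0) w / nw else w
  obj$design <- predict(obj, x)
  obj
}

# PC score matrix of new rows under a fitted reduced_design.
pc_scores <- function(object, newx) {
  newx <- as.matrix(newx)[, object$keep, drop = FALSE]
  newx <- sweep(newx, 2, object$center, "-")
  if (!isFALSE(object$scale)) newx <- sweep(newx, 2, object$scale, "/")
  newx %*% object$rotation
}

#' Apply a fitted reduced design to new rows
#'
#' @param object A [fit_reduced_design()] result.
#' @param newdata Feature matrix/data.frame with the original columns.
#' @param ... Unused.
#' @return Numeric matrix with `n_pc + 1` columns (`PC1..PCk`, `PLS1`).
#' @export
predict.reduced_design <- function(object, newdata, ...) {
  s <- pc_scores(object, newdata)
  cbind(s, PLS1 = as.numeric(s %*% object$pls_weight))
}

#' @export
print.reduced_design <- function(x, ...) {
  cat(sprintf("<reduced_design: %d/%d columns kept, %d PCs (%d degenerate) + 1 PLS-DA axis>\n",
              sum(x$keep), length(x$keep), x$n_pc, x$degenerate_axes))
  invisible(x)
}

#' Train the random-forest efficiency classifier
#'
#' Fits a seeded random forest on a reduced design matrix and binary
#' labels. Defaults are conventional for a low-dimensional design: 100
#' trees, unlimited depth, `floor(sqrt(p))` candidate variables per
#' split. Identical data, hyperparameters and seed give identical
#' predictions.
#'
#' @param design Design matrix (e.g. the `design` of
#'   [fit_reduced_design()]).
#' @param y Binary 0/1 labels, both classes present.
#' @param ntree Number of trees.
#' @param mtry Variables per split; default `floor(sqrt(ncol(design)))`.
#' @param seed Integer seed for the forest's randomness.
#' @return Object of class `"efficiency_rf"`.
#' @examples
#' x <- matrix(rnorm(60 * 4), 60); y <- rep(0:1, each = 30)
#' rf <- train_classifier(x, y, ntree = 50, seed = 1)
#' range(predict_scores(rf, x))
#' @export
train_classifier <- function(design, y, ntree = 100, mtry = NULL, seed = 1L) {
  design <- as.matrix(design)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stopf("training labels contain a single class; cannot train a classifier")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(design))))
  fac <- factor(y, levels = c(0L, 1L))
  forest <- local_seed(seed,
    randomForest::randomForest(x = design, y = fac, ntree = ntree, mtry = mtry))
  structure(list(forest = forest, ntree = ntree, mtry = mtry,
                 seed = as.integer(seed)),
            class = "efficiency_rf")
}

#' Predicted positive-class scores
#'
#' @param model An [train_classifier()] result.
#' @param design_rows Design matrix rows to score (same columns as in
#'   training).
#' @return Numeric scores in \[0, 1\] (fraction of trees voting for the
#'   positive class).
#' @export
predict_scores <- function(model, design_rows) {
  if (!inherits(model, "efficiency_rf") || is.null(model$forest))
    stopf("`model` is not a fitted efficiency classifier")
  prob <- stats::predict(model$forest, as.matrix(design_rows), type = "prob")
  as.numeric(prob[, "1"])
}

#' Threshold scores into binary predictions
#'
#' Scores greater than or equal to the threshold are predicted positive
#' (the tie at exactly the threshold goes to the positive class).
#'
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision threshold, default 0.5.
#' @return Integer 0/1 predictions.
#' @examples
#' classify(c(0.2, 0.5, 0.8))
#' @export
classify <- function(scores, threshold = 0.5) {
  as.integer(scores >= threshold)
}

#' Fit the full feature-to-score pipeline
#'
#' Convenience wrapper tying the pieces together exactly as they are used
#' inside cross-validation: constant-column removal + PCA + PLS-DA
#' reduction fitted on the training rows, then the random forest on the
#' reduced design. `predict()` maps new feature rows to positive-class
#' scores.
#'
#' @inheritParams fit_reduced_design
#' @inheritParams train_classifier
#' @return Object of class `"efficiency_model"`.
#' @export
train_efficiency_model <- function(x, y, n_pc = 10, scale = FALSE,
                                   ntree = 100, mtry = NULL, seed = 1L) {
  rd <- fit_reduced_design(x, y, n_pc = n_pc, scale = scale)
  rf <- train_classifier(rd$design, y, ntree = ntree, mtry = mtry, seed = seed)
  structure(list(reduction = rd, forest = rf), class = "efficiency_model")
}

#' @export
predict.efficiency_model <- function(object, newdata, ...) {
  predict_scores(object$forest, predict(object$reduction, newdata))
}
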