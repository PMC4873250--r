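# Confusion-count semantics, the four headline metrics
# (sensitivity/specificity/accuracy in percent, MCC), ROC/AUC, stratified
# five-fold and leave-one-out cross-validation, and grid search.

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts. At tier 1 "positive"
#'   means HSP; at tier 2 it means the family under test.
#' @return Object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Tally a confusion matrix
#'
#' @param actual,predicted Aligned label vectors (any comparable type).
#' @param positive The label counted as positive.
#' @return A [confusion_counts()].
#' @export
tally_confusion <- function(actual, predicted, positive) {
  if (length(actual) != length(predicted)) stop("label vectors must align")
  if (length(actual) == 0L) stop("empty label vectors")
  ap <- actual == positive
  pp <- predicted == positive
  confusion_counts(tp = sum(ap & pp), tn = sum(!ap & !pp),
                   fp = sum(!ap & pp), fn = sum(ap & !pp))
}

#' Compute sensitivity, specificity, accuracy and MCC
#'
#' Sensitivity = 100 TP/(TP+FN), specificity = 100 TN/(TN+FP), accuracy =
#' 100 (TP+TN)/n, and the Matthews correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Degenerate cases: a sensitivity or specificity whose class is absent is
#' reported `NA` with a warning; an MCC with any zero marginal is 0 (the
#' standard convention).
#'
#' @param counts A [confusion_counts()].
#' @param auc Optional AUC to carry in the report.
#' @return Object of class `metrics_report`: list with `sensitivity`,
#'   `specificity`, `accuracy` (percent), `mcc`, `auc`.
#' @export
compute_metrics <- function(counts, auc = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  if (n < 1) stop("confusion total must be >= 1")
  sens <- if (tp + fn == 0) {
    warning("no positive examples: sensitivity undefined"); NA_real_
  } else 100 * tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative examples: specificity undefined"); NA_real_
  } else 100 * tn / (tn + fp)
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = 100 * (tp + tn) / n, mcc = mcc, auc = auc,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sens %.2f  Spec %.2f  Accu %.2f  MCC %.3f  AUC %s\n",
              x$sensitivity, x$specificity, x$accuracy, x$mcc,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' ROC curve
#'
#' Sensitivity (true positive rate) against false positive rate as the
#' decision threshold sweeps over the distinct score values, from (0, 0) to
#' (1, 1). Both coordinates are monotone non-decreasing; tied scores
#' collapse to one point.
#'
#' @param scores Finite numeric scores (larger = more positive-like).
#' @param labels Aligned labels; `positive` marks the positive class.
#' @param positive Positive label (default `1`).
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels, positive = 1) {
  if (length(scores) != length(labels)) stop("scores and labels must align")
  if (!all(is.finite(scores))) stop("scores must be finite")
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; s <- scores[ord]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- !duplicated(s, fromLast = TRUE) # last index of each tied block
  data.frame(fpr = c(0, fp[last] / sum(!pos)),
             tpr = c(0, tp[last] / sum(pos)))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under [roc_curve()], which equals the Mann-Whitney
#' pair-counting statistic: the fraction of (positive, negative) pairs
#' ordered correctly, ties counting one half.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = 1) {
  r <- roc_curve(scores, labels, positive)
  sum(diff(r$fpr) * (head(r$tpr, -1) + r$tpr[-1]) / 2)
}

#' Build a cross-validation plan
#'
#' `five_fold`: stratified assignment — within each class, indices are
#' shuffled (seeded) and dealt round-robin into 5 folds, so per-class fold
#' counts differ by at most 1. `loocv`: n singleton folds.
#'
#' @param labels Class labels, one per record.
#' @param scheme `"five_fold"` or `"loocv"`.
#' @param seed Integer controlling the (stratified) shuffle.
#' @return Object of class `cv_plan`: list with `scheme`, `folds` (integer
#'   fold id per record), `n_folds`, `stratified`, `seed`.
#' @export
make_cv_plan <- function(labels, scheme = c("five_fold", "loocv"), seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(labels)
  if (scheme == "five_fold" && n < 5L) stop("five_fold needs n >= 5")
  if (scheme == "loocv" && n < 2L) stop("loocv needs n >= 2")
  folds <- integer(n)
  if (scheme == "loocv") {
    folds <- seq_len(n)
  } else {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(5L), length(idx))
    }
  }
  structure(list(scheme = scheme, folds = folds,
                 n_folds = if (scheme == "loocv") n else 5L,
                 stratified = scheme == "five_fold", seed = as.integer(seed)),
            class = "cv_plan")
}

.save_rng <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Cross-validate a binary classifier
#'
#' For each fold, trains on the complement and scores the held-out fold.
#' Confusion counts are pooled (micro-averaged) across folds into one
#' [compute_metrics()] report; held-out decision values are concatenated for
#' the AUC. Per-fold counts are also returned.
#'
#' @param records A [protein_set()] (or a pre-encoded feature matrix).
#' @param labels +1 / -1 vector aligned with records.
#' @param encoding `"coupled"` or `"discrete"` (ignored when `records` is
#'   already a matrix).
#' @param config A [kernel_config()].
#' @param plan A [make_cv_plan()] covering exactly these records.
#' @param seed Forwarded to [train_binary()].
#' @param threshold Decision threshold for labelling held-out scores.
#' @return List: `metrics` (pooled report incl. AUC), `per_fold` (list of
#'   `confusion_counts`), `scores` and `predicted` in record order.
#' @export
cross_validate <- function(records, labels, encoding = "coupled",
                           config = kernel_config(), plan, seed = 1L,
                           threshold = 0) {
  features <- if (is.matrix(records)) records else
    encode_dataset(records, encoding)$features
  labels <- as.numeric(labels)
  stopifnot(inherits(plan, "cv_plan"))
  if (length(plan$folds) != nrow(features)) {
    stop("cv plan does not cover these records")
  }
  scores <- numeric(nrow(features))
  per_fold <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    test <- which(plan$folds == f)
    train <- which(plan$folds != f)
    if (length(unique(labels[train])) < 2L) {
      stop("fold ", f, " leaves a single-class training set")
    }
    model <- train_binary(features[train, , drop = FALSE], labels[train],
                          config, seed = seed)
    scores[test] <- decision_value(model, features[test, , drop = FALSE])
    pred_f <- ifelse(scores[test] >= threshold, 1, -1)
    per_fold[[f]] <- tally_confusion(labels[test], pred_f, positive = 1)
  }
  predicted <- ifelse(scores >= threshold, 1, -1)
  pooled <- tally_confusion(labels, predicted, positive = 1)
  metrics <- compute_metrics(pooled, auc = auc(scores, labels, positive = 1))
  list(metrics = metrics, per_fold = per_fold, scores = scores,
       predicted = predicted)
}

#' Default hyper-parameter grid
#'
#' Polynomial degrees 1-5 and rbf gammas {5e-4, 5e-3, 1e-2, 5e-2, 1e-1},
#' crossed with cost ratios {1, 2, 4, 5, 7, 10, 20, 40} — ranges bracketing
#' the published winning parameter values for both tiers.
#'
#' @param C Soft-margin trade-off shared by all grid points.
#' @return List of [kernel_config()] objects.
#' @export
default_grid <- function(C = 1) {
  grid <- list()
  for (j in c(1, 2, 4, 5, 7, 10, 20, 40)) {
    for (d in 1:5) {
      grid[[length(grid) + 1L]] <-
        kernel_config("polynomial", degree = d, cost_ratio = j, C = C)
    }
    for (g in c(5e-4, 5e-3, 1e-2, 5e-2, 1e-1)) {
      grid[[length(grid) + 1L]] <-
        kernel_config("rbf", gamma = g, cost_ratio = j, C = C)
    }
  }
  grid
}

#' Grid search over kernel configurations
#'
#' Evaluates every configuration by [cross_validate()] and selects the
#' maximum pooled accuracy, ties broken by maximum MCC, then by grid order.
#'
#' @inheritParams cross_validate
#' @param grid Non-empty list of [kernel_config()] objects.
#' @return List: `best` (the winning config), `best_metrics`, `table`
#'   (data.frame of config descriptions and pooled metrics in grid order).
#' @export
grid_search <- function(records, labels, encoding = "coupled",
                        grid = default_grid(), plan, seed = 1L) {
  if (length(grid) == 0L) stop("empty grid")
  features <- if (is.matrix(records)) records else
    encode_dataset(records, encoding)$features
  rows <- vector("list", length(grid))
  reports <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    cfg <- grid[[k]]
    cv <- cross_validate(features, labels, encoding, cfg, plan, seed)
    reports[[k]] <- cv$metrics
    rows[[k]] <- data.frame(
      kernel = cfg$kernel, degree = cfg$degree, gamma = cfg$gamma,
      cost_ratio = cfg$cost_ratio, C = cfg$C,
      sensitivity = cv$metrics$sensitivity,
      specificity = cv$metrics$specificity,
      accuracy = cv$metrics$accuracy,
      mcc = cv$metrics$mcc, auc = cv$metrics$auc)
  }
  table <- do.call(rbind, rows)
  best_k <- order(-table$accuracy, -table$mcc, seq_len(nrow(table)))[1L]
  list(best = grid[[best_k]], best_metrics = reports[[best_k]],
       best_index = best_k, table = table)
}
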