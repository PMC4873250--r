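# Confusion tallies, metric formulas, ROC/AUC, CV plans and grid search.

test_that("confusion tallies enumerate the four categories", {
  allpos <- tally_confusion(rep(1, 5), rep(1, 5), positive = 1)
  expect_equal(unlist(allpos[c("tp", "tn", "fp", "fn")]),
               c(tp = 5, tn = 0, fp = 0, fn = 0))
  mixed <- tally_confusion(c(1, 1, -1, -1), c(1, -1, -1, 1), positive = 1)
  expect_equal(unlist(mixed[c("tp", "tn", "fp", "fn")]),
               c(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_error(tally_confusion(1:3, 1:2, positive = 1), "align")
  expect_error(tally_confusion(numeric(0), numeric(0), positive = 1), "empty")
})

test_that("metrics match the defining formulas on worked counts", {
  perfect <- compute_metrics(confusion_counts(10, 10, 0, 0))
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  m <- compute_metrics(confusion_counts(tp = 50, tn = 80, fp = 20, fn = 10))
  expect_equal(m$sensitivity, 100 * 50 / 60)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 81.25)
  # direct evaluation of the MCC formula on these counts
  expect_equal(m$mcc, (50 * 80 - 20 * 10) / sqrt(70 * 60 * 100 * 90))
})

test_that("degenerate denominators follow the documented conventions", {
  expect_warning(m <- compute_metrics(confusion_counts(0, 5, 5, 0)),
                 "sensitivity")
  expect_true(is.na(m$sensitivity))
  expect_equal(m$mcc, 0) # zero marginal -> 0 by convention
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), ">= 1")
  expect_error(confusion_counts(-1, 0, 0, 0))
})

test_that("metric identities hold over random confusion counts", {
  set.seed(99)
  for (k in 1:50) {
    cts <- sample(0:40, 4, replace = TRUE)
    if (sum(cts) == 0) next
    m <- suppressWarnings(
      compute_metrics(confusion_counts(cts[1], cts[2], cts[3], cts[4])))
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    # inverting all predictions swaps tp<->fn, tn<->fp and negates mcc
    inv <- suppressWarnings(
      compute_metrics(confusion_counts(cts[4], cts[3], cts[2], cts[1])))
    expect_equal(inv$mcc, -m$mcc, tolerance = 1e-12)
    if (!is.na(m$sensitivity)) {
      tp <- cts[1]; fn <- cts[4]
      expect_equal(m$sensitivity + 100 * fn / (tp + fn), 100)
    }
  }
})

test_that("ROC endpoints, tie handling and the worked AUC example", {
  sep <- roc_curve(c(5, 4, 1, 0), c(1, 1, -1, -1))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))
  expect_equal(auc(c(5, 4, 1, 0), c(1, 1, -1, -1)), 1)

  flat <- roc_curve(rep(2, 6), c(1, 1, 1, -1, -1, -1))
  expect_equal(flat, data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  expect_equal(auc(rep(2, 6), c(1, 1, 1, -1, -1, -1)), 0.5)

  expect_equal(auc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, -1, -1)), 0.75)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")
})

test_that("ROC curves are monotone and AUC matches pair counting", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(4:12, 1)
    labels <- c(1, -1, sample(c(1, -1), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, 0.25), n, replace = TRUE) # ties likely
    r <- roc_curve(scores, labels)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
    expect_equal(auc(scores, labels), paircount_auc(scores, labels),
                 tolerance = 1e-12)
    # negating scores complements the AUC
    expect_equal(auc(-scores, labels), 1 - auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("five-fold plans stratify within one record per class", {
  labels <- rep(c("a", "b"), each = 10)
  plan <- make_cv_plan(labels, "five_fold", seed = 4)
  expect_equal(plan$n_folds, 5L)
  tab <- table(plan$folds, labels)
  expect_true(all(tab == 2)) # 10 + 10 split exactly 2 + 2 per fold
  # uneven classes: per-class fold counts differ by at most 1
  labels2 <- c(rep("a", 13), rep("b", 9))
  plan2 <- make_cv_plan(labels2, "five_fold", seed = 4)
  tab2 <- table(factor(plan2$folds, levels = 1:5), labels2)
  expect_lte(max(tab2[, 1]) - min(tab2[, 1]), 1)
  expect_lte(max(tab2[, 2]) - min(tab2[, 2]), 1)
  # deterministic given the seed
  expect_identical(plan$folds, make_cv_plan(labels, "five_fold", 4)$folds)
})

test_that("loocv emits n singleton folds and small n errors", {
  plan <- make_cv_plan(rep(c(1, -1), length.out = 7), "loocv")
  expect_equal(plan$n_folds, 7L)
  expect_equal(sort(unique(plan$folds)), 1:7)
  expect_true(all(table(plan$folds) == 1))
  expect_error(make_cv_plan(c(1, 1, -1), "five_fold"), "n >= 5")
  expect_error(make_cv_plan(1, "loocv"), "n >= 2")
})

test_that("cross-validation pools fold counts and conserves n", {
  set.seed(2)
  gA <- make_family_generator("A", residue_bias = c(W = 8),
                              length_range = c(40L, 80L))
  gB <- make_family_generator("B", length_range = c(40L, 80L))
  recs <- .rbind_sets(sample_records(gA, 20, seed = 1),
                      sample_records(gB, 20, seed = 2))
  labels <- rep(c(1, -1), each = 20)
  plan <- make_cv_plan(labels, "five_fold", seed = 9)
  cv <- cross_validate(recs, labels, "discrete", kernel_config("linear"),
                       plan, seed = 1)
  expect_equal(cv$metrics$accuracy, 100)
  totals <- vapply(cv$per_fold, function(c) c$tp + c$tn + c$fp + c$fn,
                   numeric(1))
  expect_equal(sum(totals), 40)
  expect_length(cv$per_fold, 5L)
  expect_error(cross_validate(recs, labels, "discrete",
                              kernel_config("linear"),
                              make_cv_plan(labels[1:10], "five_fold"), 1),
               "cover")
})

test_that("label-shuffled data yields near-zero pooled MCC", {
  gA <- make_family_generator("A", residue_bias = c(W = 8),
                              length_range = c(40L, 80L))
  gB <- make_family_generator("B", length_range = c(40L, 80L))
  feats <- encode_dataset(.rbind_sets(sample_records(gA, 20, seed = 5),
                                      sample_records(gB, 20, seed = 6)),
                          "discrete")$features
  set.seed(77)
  mccs <- replicate(20, {
    labels <- sample(rep(c(1, -1), each = 20))
    plan <- make_cv_plan(labels, "five_fold", seed = sample.int(1e6, 1))
    cross_validate(feats, labels, "discrete", kernel_config("linear"),
                   plan, seed = 1)$metrics$mcc
  })
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("grid search ranks configurations by pooled accuracy", {
  gA <- make_family_generator("A", residue_bias = c(W = 8),
                              length_range = c(40L, 80L))
  gB <- make_family_generator("B", length_range = c(40L, 80L))
  recs <- .rbind_sets(sample_records(gA, 15, seed = 3),
                      sample_records(gB, 15, seed = 4))
  labels <- rep(c(1, -1), each = 15)
  plan <- make_cv_plan(labels, "five_fold", seed = 2)

  single <- grid_search(recs, labels, "discrete",
                        grid = list(kernel_config("linear")), plan = plan)
  expect_equal(single$best$kernel, "linear")

  # an rbf with absurd gamma collapses to memorization and loses
  good <- kernel_config("linear")
  bad <- kernel_config("rbf", gamma = 1e4)
  gs <- grid_search(recs, labels, "discrete", grid = list(bad, good),
                    plan = plan)
  expect_equal(gs$table$accuracy[2], max(gs$table$accuracy))
  expect_identical(gs$best$kernel, "linear")
  expect_equal(nrow(gs$table), 2L)
  expect_error(grid_search(recs, labels, "discrete", grid = list(),
                           plan = plan), "empty grid")
})

test_that("default grid brackets the published parameter vocabulary", {
  grid <- default_grid()
  degrees <- unique(stats::na.omit(vapply(grid, `[[`, 1, "degree")))
  gammas <- unique(stats::na.omit(vapply(grid, `[[`, 1.0, "gamma")))
  js <- unique(vapply(grid, `[[`, 1.0, "cost_ratio"))
  expect_true(all(c(1, 2, 3, 4, 5) %in% degrees))
  expect_true(all(c(5e-4, 5e-3, 1e-2) %in% gammas))
  expect_true(all(c(1, 4, 5, 7, 10, 20) %in% js))
})
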