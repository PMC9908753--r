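test_that("confusion_counts matches a brute-force tally", {
  truth <- rep(c("MDD", "NC"), each = 5)
  allright <- confusion_counts(truth, truth)
  expect_equal(unclass(allright)[c("TP", "TN", "FP", "FN")],
               list(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  allmdd <- confusion_counts(rep("MDD", 10), truth)
  expect_equal(allmdd$TP, 5); expect_equal(allmdd$FP, 5)
  expect_equal(allmdd$TN + allmdd$FN, 0)

  set.seed(12)
  for (rep in 1:20) {
    tr <- sample(c("MDD", "NC"), 20, replace = TRUE)
    pr <- sample(c("MDD", "NC"), 20, replace = TRUE)
    cc <- confusion_counts(pr, tr)
    tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    for (i in 1:20) {
      key <- if (tr[i] == "MDD" && pr[i] == "MDD") "TP"
        else if (tr[i] == "NC" && pr[i] == "NC") "TN"
        else if (pr[i] == "MDD") "FP" else "FN"
      tally[key] <- tally[key] + 1
    }
    expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]), tally)
    expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 20)
  }
  expect_error(confusion_counts(c("MDD"), truth), "length")
})

test_that("classification_metrics reproduces hand-computed percentages", {
  m <- classification_metrics(list(TP = 30, FN = 10, TN = 40, FP = 20))
  expect_equal(m$ACC, 70)
  expect_equal(m$SEN, 75)
  expect_equal(m$SPE, 200 / 3, tolerance = 1e-12)
  expect_equal(m$PRE, 60)
  expect_equal(m$F1, 200 / 3, tolerance = 1e-12)

  perfect <- classification_metrics(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_true(all(unlist(perfect[c("ACC", "SEN", "SPE", "PRE", "F1")]) == 100))

  # zero denominators surface as NaN, never silent zeros
  nopos <- classification_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.nan(nopos$SEN) && is.nan(nopos$PRE))
  expect_error(classification_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "zero")
})

test_that("both F1 forms agree on random counts", {
  set.seed(44)
  for (rep in 1:50) {
    cts <- as.list(stats::setNames(sample(1:60, 4, replace = TRUE),
                                   c("TP", "TN", "FP", "FN")))
    m <- classification_metrics(cts)
    harmonic <- 2 * m$PRE * m$SEN / (m$PRE + m$SEN)
    expect_equal(m$F1, harmonic, tolerance = 1e-10)
    expect_equal(m$F1, 100 * 2 * cts$TP / (2 * cts$TP + cts$FP + cts$FN),
                 tolerance = 1e-10)
  }
})

test_that("roc_auc equals the Mann-Whitney pair statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.6, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")

  set.seed(321)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), sample(c(1, 2, 6), 1))   # coarse rounding makes ties
    expect_equal(roc_auc(s, y), oracle_mann_whitney(s, y), tolerance = 1e-12)
  }
})

test_that("roc_curve spans (0,0) to (1,1) and is monotone", {
  set.seed(9)
  s <- runif(30); y <- sample(0:1, 30, replace = TRUE, prob = c(.4, .6))
  ro <- roc_curve(s, y)
  expect_equal(ro$fpr[1], 0); expect_equal(ro$tpr[1], 0)
  expect_equal(ro$fpr[nrow(ro)], 1); expect_equal(ro$tpr[nrow(ro)], 1)
  expect_true(all(diff(ro$fpr) >= 0) && all(diff(ro$tpr) >= 0))
})

test_that("holdout_split is stratified, exhaustive and reproducible", {
  labels <- c(rep("MDD", 830), rep("NC", 771))
  sp <- holdout_split(labels, 0.9, seed = 42)
  expect_equal(length(sp$train), 1441)
  expect_equal(length(sp$test), 160)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_identical(sp, holdout_split(labels, 0.9, seed = 42))
  expect_false(identical(sp$train, holdout_split(labels, 0.9, seed = 43)$train))

  # class proportions preserved within one subject on small cohorts
  for (seed in 1:5) {
    lab <- c(rep("MDD", 13), rep("NC", 7))
    s <- holdout_split(lab, 0.8, seed = seed)
    n_mdd_train <- sum(lab[s$train] == "MDD")
    expect_lte(abs(n_mdd_train - 0.8 * 13), 1)
    expect_equal(length(s$train), round(0.8 * 20))
  }
  expect_error(holdout_split(c("MDD", "NC"), 0.9), "at least 2")
})

test_that("stratified_folds partition subjects with balanced classes", {
  labels <- rep(c("MDD", "NC"), each = 50)
  fold <- stratified_folds(labels, 10, seed = 1)
  expect_equal(as.numeric(table(fold)), rep(10, 10))
  for (f in 1:10) {
    expect_equal(sum(labels[fold == f] == "MDD"), 5)
  }
  expect_error(stratified_folds(rep("MDD", 5), 10), "fewer subjects")
})

test_that("kfold_cv partitions subjects and aggregates fold metrics", {
  graphs <- tiny_graphs(n_subj = 40, n_rois = 10, T_len = 80, delta = 0.5,
                        seed = 21)
  cv <- kfold_cv(graphs, k = 5, seed = 3, trainer = centroid_trainer())
  expect_equal(length(cv$per_fold), 5)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  expect_equal(length(cv$fold_assignment), 40)
  # every subject tested exactly once
  expect_equal(sort(cv$predictions$subject_id),
               sort(vapply(graphs, function(g) g$subject_id, character(1))))
  fold_mat <- vapply(cv$per_fold, function(m) unlist(m[c("ACC", "SEN", "SPE")]),
                     numeric(3))
  expect_equal(cv$aggregate$ACC, mean(fold_mat["ACC", ]))
  expect_true(cv$pooled$ACC >= 0 && cv$pooled$ACC <= 100)
})

test_that("leave_one_site_out never leaks the held-out site into training", {
  graphs <- tiny_graphs(n_subj = 36, n_rois = 10, T_len = 80, delta = 0.5,
                        seed = 13)
  seen <- new.env()
  spy_trainer <- function(gs) {
    trained_sites <- unique(vapply(gs, function(g) g$site_id, character(1)))
    assign(paste(sort(trained_sites), collapse = ","), TRUE, envir = seen)
    centroid_trainer()(gs)
  }
  res <- leave_one_site_out(graphs, trainer = spy_trainer)
  sites <- unique(vapply(graphs, function(g) g$site_id, character(1)))
  expect_setequal(names(res$per_fold), sites)
  # each training call saw every site except exactly one
  for (nm in ls(seen)) {
    expect_equal(length(strsplit(nm, ",")[[1]]), length(sites) - 1)
  }
  # each site tested exactly once, all subjects covered
  expect_equal(sort(unique(res$predictions$site)), sort(sites))
  expect_equal(nrow(res$predictions), length(graphs))

  single <- Filter(function(g) g$site_id == sites[1], graphs)
  expect_error(leave_one_site_out(single, trainer = spy_trainer), "2 sites")
})

test_that("site-heterogeneous cohorts show more cross-site variance than homogeneous", {
  make_acc <- function(shift, seed) {
    spec <- synthetic_cohort_spec(n_per_group = 48, n_rois = 12, T_len = 100,
                                  n_blocks = 3, effect_delta = 0.35,
                                  site_count = 4, site_shift = shift,
                                  seed = seed)
    graphs <- cohort_to_graphs(generate_cohort(spec), 0.3)
    res <- leave_one_site_out(graphs, trainer = centroid_trainer())
    vapply(res$per_fold, function(m) m$ACC, numeric(1))
  }
  sd_het <- sd(make_acc(0.35, 88))
  sd_hom <- sd(make_acc(0, 88))
  expect_gt(sd_het, sd_hom)
})

test_that("a label-permuted classifier sits at chance on a balanced cohort", {
  set.seed(77)
  graphs <- tiny_graphs(n_subj = 80, n_rois = 10, T_len = 80, delta = 0.4,
                        seed = 31)
  shuffled <- sample(vapply(graphs, function(g) g$label, character(1)))
  for (i in seq_along(graphs)) graphs[[i]]$label <- shuffled[i]
  cv <- kfold_cv(graphs, k = 5, seed = 7, trainer = centroid_trainer())
  # 80 subjects: 3 binomial sd of 50% is ~16.8 points
  expect_lt(abs(cv$pooled$ACC - 50), 3 * 100 * sqrt(0.25 / 80))
})
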