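#' Confusion counts
#'
#' Tallies true/false positives and negatives. MDD is the positive class by
#' default, so sensitivity measures the MDD detection rate.
#'
#' @param predicted,truth Character vectors of labels ("MDD"/"NC"), equal
#'   length.
#' @param positive Positive-class label.
#' @return List of class `confusion_counts` with integers `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, truth, positive = "MDD") {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth lengths differ", call. = FALSE)
  }
  pred_pos <- as.character(predicted) == positive
  true_pos <- as.character(truth) == positive
  structure(list(TP = sum(pred_pos & true_pos),
                 TN = sum(!pred_pos & !true_pos),
                 FP = sum(pred_pos & !true_pos),
                 FN = sum(!pred_pos & true_pos)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision and F1, all as percentages:
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)`, `SPE = TN/(TN+FP)`,
#' `PRE = TP/(TP+FP)`, `F1 = 2*PRE*SEN/(PRE+SEN) = 2TP/(2TP+FP+FN)`.
#' A ratio with a zero denominator is reported as `NaN`, never silently 0.
#'
#' @param counts A `confusion_counts` object or list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @param auc Optional AUC (in \[0, 1\]) to carry alongside the percentage
#'   metrics.
#' @return List of class `metrics_report` with `ACC`, `SEN`, `SPE`, `PRE`,
#'   `F1` (percent) and `AUC`.
#' @export
classification_metrics <- function(counts, auc = NA_real_) {
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  n <- tp + tn + fp + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NaN else num / den
  sen <- ratio(tp, tp + fn)
  pre <- ratio(tp, tp + fp)
  structure(list(
    ACC = 100 * (tp + tn) / n,
    SEN = 100 * sen,
    SPE = 100 * ratio(tn, tn + fp),
    PRE = 100 * pre,
    F1 = 100 * ratio(2 * tp, 2 * tp + fp + fn),
    AUC = auc), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("ACC %.1f%%  SEN %.1f%%  SPE %.1f%%  PRE %.1f%%  F1 %.1f%%  AUC %s\n",
              x$ACC, x$SEN, x$SPE, x$PRE, x$F1,
              if (is.na(x$AUC)) "NA" else sprintf("%.3f", x$AUC)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Traces the ROC curve over all unique score thresholds and integrates it
#' with the trapezoidal rule. With midrank handling of ties this equals the
#' Mann-Whitney statistic: the fraction of positive-negative pairs ordered
#' correctly, ties counted 1/2.
#'
#' @param scores Numeric scores (higher = more positive-like), e.g. the
#'   positive-class probability.
#' @param labels 0/1 vector (1 = positive); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- as.numeric(labels)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to trace a ROC curve", call. = FALSE)
  }
  ro <- roc_curve(scores, y)
  # trapezoid over the (FPR, TPR) polyline
  sum(diff(ro$fpr) * (utils::head(ro$tpr, -1) + utils::tail(ro$tpr, -1)) / 2)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return `data.frame` with `threshold`, `fpr`, `tpr`, from (0, 0) to
#'   (1, 1).
#' @export
roc_curve <- function(scores, labels) {
  y <- as.numeric(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  keep <- c(s[-length(s)] != s[-1], TRUE)   # last index of each unique score
  tp <- cumsum(y)[keep]
  fp <- cumsum(1 - y)[keep]
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fp / sum(labels == 0)),
             tpr = c(0, tp / sum(labels == 1)))
}

#' Stratified holdout split
#'
#' Randomly splits subject indices into train/test, stratified by label: the
#' total train size is `round(train_fraction * n)` and each class contributes
#' its proportional share (largest-remainder rounding reconciles the class
#' totals with the overall size).
#'
#' @param labels Character vector of subject labels.
#' @param train_fraction Fraction assigned to training (default 0.9).
#' @param seed Integer RNG seed for the split.
#' @return List with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
holdout_split <- function(labels, train_fraction = 0.9, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every class needs at least 2 members to split", call. = FALSE)
  }
  target <- round(train_fraction * n)
  exact <- stats::setNames(train_fraction * as.numeric(tab), names(tab))
  base <- floor(exact)
  rem <- target - sum(base)
  # hand the leftover slots to the classes with the largest fractional parts
  frac_order <- order(exact - base, decreasing = TRUE)
  sizes <- base
  if (rem > 0) sizes[frac_order[seq_len(rem)]] <- sizes[frac_order[seq_len(rem)]] + 1
  if (rem < 0) sizes[rev(frac_order)[seq_len(-rem)]] <- sizes[rev(frac_order)[seq_len(-rem)]] - 1
  set.seed(seed)
  train <- integer(0)
  for (cl in names(tab)) {
    ix <- which(labels == cl)
    train <- c(train, sample(ix, sizes[cl]))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Stratified fold assignment
#'
#' @param labels Character vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector in `1..k`, one entry per subject; class-stratified.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < k) stop("fewer subjects (", n, ") than folds (", k, ")", call. = FALSE)
  set.seed(seed)
  fold <- integer(n)
  for (cl in unique(labels)) {
    ix <- sample(which(labels == cl))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

# default trainer/predictor pair: DGCNN
dgcnn_trainer <- function(config) {
  function(graphs) train_dgcnn(graphs, config = config)
}

default_predictor <- function(model, graphs) {
  stats::predict(model, graphs)
}

#' Nearest-centroid baseline trainer
#'
#' A deliberately simple pluggable classifier for exercising the evaluation
#' harness cheaply: vectorizes each graph's upper-triangle node features,
#' stores the two class centroids, and scores a subject by its difference in
#' Euclidean distance to them (mapped through a logistic to a pseudo
#' probability).
#'
#' @return A trainer `function(graphs) -> model` usable by [kfold_cv()] and
#'   [leave_one_site_out()].
#' @export
centroid_trainer <- function() {
  featurize <- function(g) g$features[upper.tri(g$features)]
  function(graphs) {
    x <- do.call(rbind, lapply(graphs, featurize))
    y <- vapply(graphs, function(g) g$label, character(1))
    if (length(unique(y)) < 2) stop("training set must contain both classes",
                                    call. = FALSE)
    model <- list(mu_pos = colMeans(x[y == "MDD", , drop = FALSE]),
                  mu_neg = colMeans(x[y == "NC", , drop = FALSE]),
                  featurize = featurize)
    class(model) <- "centroid_model"
    model
  }
}

#' @export
predict.centroid_model <- function(object, graphs, ...) {
  if (length(graphs) == 0) {
    return(data.frame(subject_id = character(0), p_NC = numeric(0),
                      p_MDD = numeric(0), pred = character(0)))
  }
  x <- do.call(rbind, lapply(graphs, object$featurize))
  dpos <- sqrt(rowSums(sweep(x, 2, object$mu_pos)^2))
  dneg <- sqrt(rowSums(sweep(x, 2, object$mu_neg)^2))
  p <- 1 / (1 + exp(dpos - dneg))
  data.frame(subject_id = vapply(graphs, function(g) g$subject_id, character(1)),
             p_NC = 1 - p, p_MDD = p,
             pred = ifelse(p >= 0.5, "MDD", "NC"))
}

fold_metrics <- function(preds, truth) {
  cc <- confusion_counts(preds$pred, truth)
  auc <- if (length(unique(truth)) == 2) {
    roc_auc(preds$p_MDD, as.numeric(truth == "MDD"))
  } else NA_real_
  classification_metrics(cc, auc = auc)
}

aggregate_cv <- function(per_fold, pooled_counts, pooled_scores, pooled_truth) {
  metric_mat <- do.call(rbind, lapply(per_fold, function(m) {
    unlist(m[c("ACC", "SEN", "SPE", "PRE", "F1", "AUC")])
  }))
  agg <- as.list(colMeans(metric_mat, na.rm = TRUE))
  class(agg) <- "metrics_report"
  pooled_auc <- if (length(unique(pooled_truth)) == 2) {
    roc_auc(pooled_scores, as.numeric(pooled_truth == "MDD"))
  } else NA_real_
  pooled <- classification_metrics(pooled_counts, auc = pooled_auc)
  list(aggregate = agg, pooled = pooled)
}

#' Stratified k-fold cross-validation
#'
#' Splits subjects into `k` class-stratified folds; each fold is held out
#' once while a model is trained from scratch on the remaining folds. The
#' aggregate report is the unweighted mean of the per-fold metrics (a pooled
#' confusion-matrix version is also returned for comparison). The model seed
#' is offset by the fold index so folds are independent yet reproducible.
#'
#' @param graphs List of `brain_graph` objects.
#' @param k Number of folds (default 10).
#' @param config A [dgcnn_config()]; used by the default DGCNN trainer and as
#'   the seed source.
#' @param seed Seed for fold assignment (defaults to `config$seed`).
#' @param trainer `function(graphs) -> model`; defaults to DGCNN training
#'   with per-fold seed offsets.
#' @param predictor `function(model, graphs) -> data.frame(p_NC, p_MDD,
#'   pred)`; defaults to [predict()].
#' @return A `cv_result`: list with `per_fold` (list of `metrics_report`),
#'   `aggregate`, `pooled`, `fold_assignment`, and `predictions`
#'   (per-subject pooled test predictions).
#' @export
kfold_cv <- function(graphs, k = 10L, config = dgcnn_config(),
                     seed = config$seed, trainer = NULL, predictor = NULL) {
  labels <- vapply(graphs, function(g) g$label, character(1))
  fold <- stratified_folds(labels, k, seed)
  predictor <- predictor %||% default_predictor
  per_fold <- vector("list", k)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  all_pred <- vector("list", k)
  for (f in seq_len(k)) {
    tr_ix <- which(fold != f)
    te_ix <- which(fold == f)
    if (length(unique(labels[tr_ix])) < 2) {
      stop("fold ", f, " leaves a single-class training set", call. = FALSE)
    }
    fit <- if (is.null(trainer)) {
      cfg <- config
      cfg$seed <- config$seed + f - 1L
      train_dgcnn(graphs[tr_ix], config = cfg)
    } else {
      trainer(graphs[tr_ix])
    }
    preds <- predictor(fit, graphs[te_ix])
    per_fold[[f]] <- fold_metrics(preds, labels[te_ix])
    cc <- confusion_counts(preds$pred, labels[te_ix])
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    all_pred[[f]] <- cbind(preds, truth = labels[te_ix], fold = f)
  }
  predictions <- do.call(rbind, all_pred)
  agg <- aggregate_cv(per_fold, pooled, predictions$p_MDD,
                      predictions$truth)
  structure(list(per_fold = per_fold, aggregate = agg$aggregate,
                 pooled = agg$pooled, fold_assignment = fold,
                 predictions = predictions),
            class = "cv_result")
}

#' Leave-one-site-out evaluation
#'
#' For each acquisition site S, trains on every subject *not* from S and
#' tests on S — the cross-site generalization protocol for multi-site
#' cohorts. Per-site metrics are returned alongside the unweighted mean and
#' the pooled-confusion aggregate.
#'
#' @inheritParams kfold_cv
#' @return A `cv_result` whose `per_fold` list is keyed by site id and which
#'   carries a `sites` character vector.
#' @export
leave_one_site_out <- function(graphs, config = dgcnn_config(),
                               trainer = NULL, predictor = NULL) {
  labels <- vapply(graphs, function(g) g$label, character(1))
  sites <- vapply(graphs, function(g) g$site_id, character(1))
  usite <- sort(unique(sites))
  if (length(usite) < 2) stop("need at least 2 sites", call. = FALSE)
  predictor <- predictor %||% default_predictor
  per_site <- stats::setNames(vector("list", length(usite)), usite)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  all_pred <- vector("list", length(usite))
  for (i in seq_along(usite)) {
    s <- usite[i]
    tr_ix <- which(sites != s)
    te_ix <- which(sites == s)
    fit <- if (is.null(trainer)) {
      cfg <- config
      cfg$seed <- config$seed + i - 1L
      train_dgcnn(graphs[tr_ix], config = cfg)
    } else {
      trainer(graphs[tr_ix])
    }
    preds <- predictor(fit, graphs[te_ix])
    per_site[[s]] <- fold_metrics(preds, labels[te_ix])
    cc <- confusion_counts(preds$pred, labels[te_ix])
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    all_pred[[i]] <- cbind(preds, truth = labels[te_ix], site = s)
  }
  predictions <- do.call(rbind, all_pred)
  agg <- aggregate_cv(per_site, pooled, predictions$p_MDD, predictions$truth)
  structure(list(per_fold = per_site, aggregate = agg$aggregate,
                 pooled = agg$pooled, sites = usite,
                 predictions = predictions),
            class = "cv_result")
}

#' Tabulate a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return `data.frame`, one row per fold/site plus `mean` and `pooled`
#'   rows, columns `ACC`, `SEN`, `SPE`, `PRE`, `F1`, `AUC`.
#' @export
as.data.frame.cv_result <- function(x, ...) {
  rows <- c(x$per_fold, list(mean = x$aggregate, pooled = x$pooled))
  out <- do.call(rbind, lapply(rows, function(m) {
    data.frame(ACC = m$ACC, SEN = m$SEN, SPE = m$SPE, PRE = m$PRE,
               F1 = m$F1, AUC = m$AUC)
  }))
  nm <- names(rows)
  if (is.null(nm) || any(nm == "")) {
    nm[seq_along(x$per_fold)] <- paste0("fold", seq_along(x$per_fold))
    nm[length(rows) - 1L] <- "mean"; nm[length(rows)] <- "pooled"
  }
  out$unit <- nm
  rownames(out) <- NULL
  out[, c("unit", "ACC", "SEN", "SPE", "PRE", "F1", "AUC")]
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds/sites\n", length(x$per_fold)))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}
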