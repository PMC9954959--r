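#' Confusion counts with malignant as the positive class
#'
#' @param truth,predicted benign/malignant factors or characters of equal
#'   length.
#' @return A `"confusion_counts"` list with integer `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% c("benign", "malignant")),
            all(predicted %in% c("benign", "malignant")))
  structure(list(
    tp = sum(truth == "malignant" & predicted == "malignant"),
    tn = sum(truth == "benign" & predicted == "benign"),
    fp = sum(truth == "benign" & predicted == "malignant"),
    fn = sum(truth == "malignant" & predicted == "benign")),
    class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity (percent)
#'
#' The three headline metrics of the evaluation protocol, with malignant as
#' the positive class:
#' `AC = (TP + TN) / (TP + TN + FP + FN) * 100`,
#' `SN = TP / (TP + FN) * 100`, `SP = TN / (TN + FP) * 100`.
#' An undefined ratio (no positives, or no negatives, among the evaluated
#' samples) is reported as `NaN` with a warning rather than silently zeroed.
#'
#' @param counts a [confusion_counts()] object or a list with `tp`, `tn`,
#'   `fp`, `fn`.
#' @return A `"metric_set"` list with `accuracy`, `sensitivity`,
#'   `specificity` in `[0, 100]`.
#' @examples
#' classification_metrics(list(tp = 25, tn = 55, fp = 6, fn = 9))
#' @export
classification_metrics <- function(counts) {
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total <= 0) stop("no evaluated samples")
  sn <- if (counts$tp + counts$fn == 0) {
    warning("no malignant samples evaluated; sensitivity undefined")
    NaN
  } else 100 * counts$tp / (counts$tp + counts$fn)
  sp <- if (counts$tn + counts$fp == 0) {
    warning("no benign samples evaluated; specificity undefined")
    NaN
  } else 100 * counts$tn / (counts$tn + counts$fp)
  structure(list(accuracy = 100 * (counts$tp + counts$tn) / total,
                 sensitivity = sn, specificity = sp),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("AC %.2f%%  SN %.2f%%  SP %.2f%%\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Data-splitting plan
#'
#' The four splitting schemes of the evaluation protocol: 70/30 and 80/20
#' holdouts and 5-/10-fold cross validation. Splits are stratified by class
#' by default: with a 28.6% benign prevalence an unstratified small test set
#' can lose one class entirely.
#'
#' @param scheme one of `"holdout_70_30"`, `"holdout_80_20"`, `"kfold_5"`,
#'   `"kfold_10"`.
#' @param seed integer seed driving the (otherwise random) assignment.
#' @param stratified preserve the class ratio within folds (default `TRUE`).
#' @return A `"split_plan"` list.
#' @export
split_plan <- function(scheme = c("holdout_70_30", "holdout_80_20",
                                  "kfold_5", "kfold_10"),
                       seed = 1, stratified = TRUE) {
  scheme <- match.arg(scheme)
  structure(list(scheme = scheme, seed = seed, stratified = stratified),
            class = "split_plan")
}

#' Generate train/test index splits
#'
#' Holdout plans return one `(train, test)` pair with the test size
#' `floor(test_fraction * n)`; k-fold plans return `k` pairs whose test folds
#' are disjoint, cover every sample, and differ in size by at most one.
#' Stratification allocates test slots per class by largest fractional
#' remainder (holdout) or deals each class round-robin across folds (k-fold).
#'
#' @param labels benign/malignant labels of the table to split (a
#'   `NoduleTable` data frame is also accepted; its `label` column is used).
#' @param plan a [split_plan()].
#' @return List of splits, each a list with integer vectors `train`, `test`.
#' @export
make_splits <- function(labels, plan) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  n <- length(labels)
  set.seed(plan$seed)
  cfg <- switch(plan$scheme,
                holdout_70_30 = list(kind = "holdout", frac = 0.30),
                holdout_80_20 = list(kind = "holdout", frac = 0.20),
                kfold_5 = list(kind = "kfold", k = 5),
                kfold_10 = list(kind = "kfold", k = 10))
  classes <- if (plan$stratified) split(seq_len(n), labels) else
    list(all = seq_len(n))

  if (cfg$kind == "holdout") {
    n_test <- floor(cfg$frac * n)
    exact <- vapply(classes, function(ix) cfg$frac * length(ix), 0)
    take <- floor(exact)
    short <- n_test - sum(take)
    if (short > 0) {
      ord <- order(exact - take, decreasing = TRUE)
      take[ord[seq_len(short)]] <- take[ord[seq_len(short)]] + 1
    }
    test <- unlist(lapply(seq_along(classes), function(i)
      sample(classes[[i]], take[i])), use.names = FALSE)
    list(list(train = sort(setdiff(seq_len(n), test)), test = sort(test)))
  } else {
    k <- cfg$k
    if (plan$stratified && any(lengths(classes) < k))
      stop("a class has fewer samples than folds; cannot stratify")
    fold_of <- integer(n)
    for (ix in classes) {
      ix <- sample(ix)
      fold_of[ix] <- rep_len(seq_len(k), length(ix))
    }
    lapply(seq_len(k), function(f)
      list(train = which(fold_of != f), test = which(fold_of == f)))
  }
}

#' Evaluate a trainer under a splitting plan
#'
#' For a holdout plan: fit on the training part (scaling, FCM initialization
#' and training all use the training part only) and compute the metrics on
#' the held-out part. For a k-fold plan: fit once per fold and, by default,
#' pool the test-fold confusion counts before computing the metrics —
#' pooling is bias-free for SN/SP when folds have unequal class counts; set
#' `per_fold = TRUE` to average per-fold percentages instead.
#'
#' @param table a `NoduleTable` data frame (`P1..P27` plus `label`), e.g.
#'   from [generate_nodules()] or [read_nodule_table()].
#' @param plan a [split_plan()].
#' @param trainer `"ga"`, `"bp"` or `"hybrid"`.
#' @param config trainer configuration; `NULL` for the study defaults.
#' @param n_rules fuzzy rules per model.
#' @param signs character vector of sign columns to use (default all 27).
#' @param per_fold average per-fold metric percentages instead of pooling
#'   counts (k-fold only).
#' @param seed seed for model initialization (split randomness is governed by
#'   `plan$seed`).
#' @return A `"metric_set"`.
#' @export
evaluate_trainer <- function(table, plan, trainer = "ga", config = NULL,
                             n_rules = 10, signs = NULL, per_fold = FALSE,
                             seed = 1) {
  signs <- if (is.null(signs)) grep("^P[0-9]+$", names(table), value = TRUE)
           else signs
  x <- as.matrix(table[signs])
  y <- as.character(table$label)
  splits <- make_splits(y, plan)

  fold_metrics <- list()
  pooled <- list(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (s in splits) {
    fit <- anfis_fit(x[s$train, , drop = FALSE], y[s$train],
                     trainer = trainer, n_rules = n_rules,
                     config = config, seed = seed)
    pred <- predict(fit$model, x[s$test, , drop = FALSE], type = "class")
    cc <- confusion_counts(y[s$test], pred)
    pooled <- Map(`+`, pooled, cc[c("tp", "tn", "fp", "fn")])
    fold_metrics <- c(fold_metrics, list(classification_metrics(cc)))
  }
  if (per_fold && length(splits) > 1) {
    aggregate_mean(fold_metrics)
  } else {
    classification_metrics(pooled)
  }
}

# round half away from zero, the convention of the report tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Average a set of metric rows
#'
#' Arithmetic mean of accuracy, sensitivity and specificity across
#' experiments (e.g. the twelve scheme-by-signset cells of one trainer),
#' reported to two decimals with half-up rounding, the convention of the
#' summary tables.
#'
#' @param metric_rows list of `"metric_set"` objects, or a data frame with
#'   columns `accuracy`, `sensitivity`, `specificity` (abbreviations
#'   `AC`/`SN`/`SP` are also accepted).
#' @return A `"metric_set"` with the rounded means.
#' @export
aggregate_mean <- function(metric_rows) {
  if (is.data.frame(metric_rows)) {
    nm <- names(metric_rows)
    col <- function(a, b) metric_rows[[if (a %in% nm) a else b]]
    ac <- col("accuracy", "AC"); sn <- col("sensitivity", "SN")
    sp <- col("specificity", "SP")
  } else {
    stopifnot(length(metric_rows) >= 1)
    ac <- vapply(metric_rows, `[[`, 0, "accuracy")
    sn <- vapply(metric_rows, `[[`, 0, "sensitivity")
    sp <- vapply(metric_rows, `[[`, 0, "specificity")
  }
  structure(list(accuracy = round_half_up(mean(ac)),
                 sensitivity = round_half_up(mean(sn)),
                 specificity = round_half_up(mean(sp))),
            class = "metric_set")
}

#' Benchmark metrics reported on the original clinical cohort
#'
#' The published per-experiment accuracy/sensitivity/specificity values of
#' the four classifiers (ANFIS trained by hybrid, backpropagation and the
#' genetic algorithm, plus a deep-network comparator) on the original
#' 398-nodule clinical cohort, across the four splitting schemes and the
#' 27/13/8-sign input sets. The clinical table itself is not distributed;
#' these cells let the aggregation step be exercised and checked against the
#' published per-classifier averages.
#'
#' @return Data frame with columns `signs`, `scheme`, `classifier`, `AC`,
#'   `SN`, `SP`.
#' @export
reference_metrics <- function() {
  path <- system.file("extdata", "reference_metrics.csv",
                      package = "anfiscad", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
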