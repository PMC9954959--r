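test_that("confusion metrics follow the percentage definitions", {
  perfect <- classification_metrics(list(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_equal(unclass(perfect)[c("accuracy", "sensitivity", "specificity")],
               list(accuracy = 100, sensitivity = 100, specificity = 100))
  worst <- classification_metrics(list(tp = 0, tn = 0, fp = 3, fn = 2))
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$specificity, 0)

  m <- classification_metrics(list(tp = 25, tn = 55, fp = 6, fn = 9))
  expect_equal(m$accuracy, 100 * 80 / 95)
  expect_equal(m$sensitivity, 100 * 25 / 34)
  expect_equal(m$specificity, 100 * 55 / 61)

  # a degenerate always-malignant classifier on the 284/114 class sizes
  deg <- classification_metrics(list(tp = 284, tn = 0, fp = 114, fn = 0))
  expect_equal(deg$sensitivity, 100)
  expect_equal(deg$specificity, 0)

  expect_warning(und <- classification_metrics(list(tp = 0, tn = 4, fp = 1,
                                                    fn = 0)),
                 "sensitivity")
  expect_true(is.nan(und$sensitivity))
})

test_that("metrics agree with a brute-force recount of prediction pairs", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 50
    truth <- sample(c("benign", "malignant"), n, TRUE)
    pred <- sample(c("benign", "malignant"), n, TRUE)
    if (length(unique(truth)) < 2) next
    cc <- confusion_counts(truth, pred)
    m <- classification_metrics(cc)
    expect_equal(m$accuracy, 100 * mean(truth == pred))
    expect_equal(m$sensitivity,
                 100 * mean(pred[truth == "malignant"] == "malignant"))
    expect_equal(m$specificity,
                 100 * mean(pred[truth == "benign"] == "benign"))
  }
})

test_that("holdout splitting yields the documented sizes and a partition", {
  labels <- rep(c("malignant", "benign"), c(284, 114))
  sp <- make_splits(labels, split_plan("holdout_70_30", seed = 5))[[1]]
  expect_length(sp$test, 119)   # floor(0.30 * 398)
  expect_length(sp$train, 279)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # stratification keeps the class ratio: 85 of 284 malignant in test
  expect_equal(sum(labels[sp$test] == "malignant"), 85)
})

test_that("k-fold splits are disjoint, covering, balanced and stratified", {
  labels <- rep(c("malignant", "benign"), c(60, 40))
  for (scheme in c("kfold_5", "kfold_10")) {
    folds <- make_splits(labels, split_plan(scheme, seed = 3))
    tests <- lapply(folds, `[[`, "test")
    expect_setequal(unlist(tests), seq_along(labels))
    expect_equal(sum(lengths(tests)), length(labels))  # disjoint + covering
    expect_lte(diff(range(lengths(tests))), 1)
    # class ratio within one sample per fold
    mal <- vapply(tests, function(ix) sum(labels[ix] == "malignant"), 0)
    expect_lte(diff(range(mal)), 1)
    for (f in folds)
      expect_setequal(c(f$train, f$test), seq_along(labels))
  }
  expect_identical(make_splits(labels, split_plan("kfold_5", seed = 8)),
                   make_splits(labels, split_plan("kfold_5", seed = 8)))
  expect_error(make_splits(rep(c("malignant", "benign"), c(97, 3)),
                           split_plan("kfold_5", seed = 1)),
               "fewer samples than folds")
})

test_that("a perfectly separating sign gives perfect metrics under all plans", {
  tbl <- generate_nodules(n_total = 120, n_malignant = 70, risk_lift = 0,
                          seed = 9)
  # overwrite the label so it is exactly indicator(P14 >= 2)
  tbl$label <- factor(ifelse(tbl$P14 >= 2, "malignant", "benign"),
                      levels = c("benign", "malignant"))
  for (scheme in c("holdout_70_30", "holdout_80_20", "kfold_5", "kfold_10")) {
    m <- evaluate_trainer(tbl, split_plan(scheme, seed = 2),
                          trainer = "hybrid",
                          config = bp_config(n_iterations = 5),
                          n_rules = 2, signs = "P14", seed = 2)
    expect_equal(m$accuracy, 100)
  }
})

test_that("evaluation is reproducible run-to-run", {
  tbl <- generate_nodules(n_total = 100, n_malignant = 65, seed = 4)
  plan <- split_plan("holdout_70_30", seed = 6)
  cfg <- ga_config(n_iterations = 5, population_size = 8, seed = 6)
  a <- evaluate_trainer(tbl, plan, trainer = "ga", config = cfg, seed = 6)
  b <- evaluate_trainer(tbl, plan, trainer = "ga", config = cfg, seed = 6)
  expect_identical(a, b)
})

test_that("aggregation averages with half-up rounding to two decimals", {
  rows <- list(
    structure(list(accuracy = 84.125, sensitivity = 70, specificity = 90),
              class = "metric_set"),
    structure(list(accuracy = 84.125, sensitivity = 71, specificity = 91),
              class = "metric_set"))
  a <- aggregate_mean(rows)
  expect_equal(a$accuracy, 84.13)  # 84.125 rounds up, not to even
  expect_equal(a$sensitivity, 70.5)
  expect_equal(a$specificity, 90.5)
  # data-frame input with abbreviated column names
  df <- data.frame(AC = c(80, 81), SN = c(60, 61), SP = c(90, 91))
  expect_equal(aggregate_mean(df)$accuracy, 80.5)
})

test_that("the shipped benchmark table has the full experiment grid", {
  ref <- reference_metrics()
  expect_equal(nrow(ref), 48)
  expect_setequal(unique(ref$classifier),
                  c("ANFIS-HB", "ANFIS-BP", "DNN", "ANFIS-GA"))
  expect_setequal(unique(ref$signs), c(27, 13, 8))
  expect_setequal(unique(ref$scheme),
                  c("holdout_70_30", "holdout_80_20", "kfold_5", "kfold_10"))
  expect_true(all(ref$AC >= 0 & ref$AC <= 100))
})
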