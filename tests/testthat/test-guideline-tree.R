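test_that("Gini impurity follows 1 - sum(p^2)", {
  expect_equal(gini(c(10, 0)), 0)
  expect_equal(gini(c(5, 5)), 0.5)
  expect_equal(gini(c(3, 1)), 0.375)
  expect_error(gini(c(0, 0)), "empty")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("best_split finds the separating code boundary", {
  set.seed(21)
  x <- cbind(P4 = sample(1:2, 40, TRUE), P5 = sample(1:8, 40, TRUE))
  y <- ifelse(x[, "P4"] == 2, "malignant", "benign")
  sp <- best_split(x, y)
  expect_equal(sp$sign, 1)
  expect_equal(sp$threshold, 1.5)
  expect_equal(sp$impurity_decrease, gini(table(y)))  # children are pure

  expect_null(best_split(x, rep("benign", 40)))

  # equal columns: the tie goes to the lower sign index
  x2 <- cbind(a = c(1, 1, 2, 2), b = c(1, 1, 2, 2))
  y2 <- c("benign", "benign", "malignant", "malignant")
  expect_equal(best_split(x2, y2)$sign, 1)
})

test_that("best_split agrees with exhaustive search on small tables", {
  set.seed(22)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    p <- sample(2:5, 1)
    x <- matrix(sample(0:4, n * p, TRUE), n, p)
    y <- sample(c("benign", "malignant"), n, TRUE)
    got <- best_split(x, y)
    want <- brute_best_split(x, y)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$sign, want$sign)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$impurity_decrease, want$impurity_decrease)
    }
  }
})

test_that("tree growth terminates at purity and respects the split budget", {
  pure <- data.frame(P2 = c(1, 2, 3), P3 = c(2, 2, 1))
  t0 <- grow_tree(pure, rep("malignant", 3))
  expect_equal(t0$n_splits, 0L)
  expect_true(t0$root$leaf)

  tbl <- generate_nodules(n_total = 200, n_malignant = 130, seed = 6)
  t7 <- grow_tree(tbl[sign_cols], tbl$label, max_splits = 7)
  expect_lte(t7$n_splits, 7L)
  expect_true(t7$pruned)

  # fully grown: every leaf is pure or admits no positive-decrease split
  tf <- grow_tree(tbl[sign_cols], tbl$label)
  x <- as.matrix(tbl[sign_cols])
  check_leaf <- function(node, ix) {
    if (node$leaf) {
      sub_y <- as.character(tbl$label)[ix]
      if (gini(table(factor(sub_y, c("benign", "malignant")))) > 0)
        expect_null(best_split(x[ix, , drop = FALSE], sub_y))
      return(invisible())
    }
    left <- x[ix, node$sign] < node$threshold
    check_leaf(node$left, ix[left])
    check_leaf(node$right, ix[!left])
  }
  check_leaf(tf$root, seq_len(nrow(x)))

  # deeper trees never have higher resubstitution loss
  expect_lte(classification_loss(tf, tbl[sign_cols], tbl$label),
             classification_loss(t7, tbl[sign_cols], tbl$label))
})

test_that("an interaction of two risk signs is recovered at depth two", {
  set.seed(23)
  n <- 200
  x <- data.frame(P2 = sample(1:9, n, TRUE), P3 = sample(1:9, n, TRUE),
                  P20 = sample(1:4, n, TRUE))
  y <- ifelse(x$P2 <= 2 & x$P3 %in% 2:3, "malignant", "benign")
  tr <- grow_tree(x, y)
  expect_lte(tr$n_splits, 3L)  # one P2 split, P3 refinements
  expect_equal(classification_loss(tr, x, y), 0)
  used <- names(tr$importance)[tr$importance > 0]
  expect_setequal(used, c("P2", "P3"))
})

test_that("majority-leaf loss matches the class imbalance", {
  tbl <- generate_nodules(n_total = 398, n_malignant = 284, risk_lift = 0,
                          seed = 11)
  stump <- grow_tree(tbl[sign_cols], tbl$label, max_splits = 0)
  expect_true(stump$root$leaf)
  expect_identical(stump$root$class, "malignant")
  expect_equal(classification_loss(stump, tbl[sign_cols], tbl$label),
               114 / 398)
})

test_that("sign importance is conserved and reflects information content", {
  tbl <- generate_nodules(n_total = 250, n_malignant = 160, seed = 12)
  rk <- rank_signs(tbl[sign_cols], tbl$label)
  expect_true(all(rk$importance >= 0))
  expect_true(all(diff(rk$importance) <= 0))
  expect_length(top_signs(rk, 13), 13)

  # conservation: importances sum to root impurity minus weighted leaf impurity
  tr <- grow_tree(tbl[sign_cols], tbl$label)
  leaves <- tree_leaves(tr$root)
  leaf_term <- sum(vapply(leaves, function(l)
    l$n / nrow(tbl) * gini(l$counts), 0))
  root_gini <- gini(table(tbl$label))
  expect_equal(sum(tr$importance), root_gini - leaf_term, tolerance = 1e-10)

  # a single fabricated informative sign dominates a null table
  set.seed(24)
  null_tbl <- generate_nodules(n_total = 250, n_malignant = 160,
                               risk_lift = 0, seed = 13)
  info <- null_tbl
  info$P6 <- ifelse(info$label == "malignant", 2, 1)
  rk_info <- rank_signs(info[sign_cols], info$label)
  rk_null <- rank_signs(null_tbl[sign_cols], null_tbl$label)
  expect_identical(rk_info$sign[1], "P6")
  p6 <- function(rk) rk$importance[rk$sign == "P6"]
  expect_gt(p6(rk_info), 3 * max(p6(rk_null), 1e-6))
})

test_that("guideline export renders the flowchart and a valid DOT graph", {
  leaf_tree <- grow_tree(data.frame(P2 = c(1, 2)), rep("benign", 2))
  expect_length(guideline_text(leaf_tree), 1L)

  set.seed(25)
  x <- data.frame(P2 = sample(1:9, 120, TRUE), P3 = sample(1:9, 120, TRUE))
  y <- ifelse(x$P2 <= 2 & x$P3 %in% 2:3, "malignant", "benign")
  tr <- grow_tree(x, y)
  txt <- guideline_text(tr)
  expect_true(any(grepl("^P2 \\[code <= 2\\]:", txt)))
  expect_true(any(grepl("P3 \\[code", txt)))
  expect_true(any(grepl("=> malignant", txt)))

  dot <- guideline_dot(tr)
  expect_match(dot, "^digraph guideline \\{")
  n_edges <- lengths(regmatches(dot, gregexpr("->", dot)))
  n_nodes <- lengths(regmatches(dot, gregexpr("label=", dot)))
  expect_equal(n_edges, 2 * tr$n_splits)
  expect_equal(n_nodes, (2 * tr$n_splits + 1) + n_edges)  # nodes + edge labels
})
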