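# Fixture builders and independent oracles shared across test files.

# random but valid ANFIS model of a given shape
rand_model <- function(n_inputs, n_rules, seed = 1) {
  set.seed(seed)
  anfis_model(
    centers = matrix(runif(n_rules * n_inputs), n_rules, n_inputs),
    sigmas = matrix(runif(n_rules * n_inputs, 0.05, 0.5), n_rules, n_inputs),
    coeffs = matrix(rnorm(n_rules * n_inputs), n_rules, n_inputs),
    bias = rnorm(n_rules))
}

# a fixed 2-rule, 2-input instance used for the hand-checkable layer tests
hand_model <- function() {
  anfis_model(centers = matrix(c(0.2, 0.7, 0.8, 0.3), 2, 2),
              sigmas = matrix(c(0.15, 0.25, 0.2, 0.1), 2, 2),
              coeffs = matrix(c(1, -2, 0.5, 3), 2, 2),
              bias = c(0.1, -0.4))
}

# Independent brute-force oracle for one input vector: direct membership
# products and plain normalization, no log-space path.
brute_wbar <- function(model, x) {
  w <- vapply(seq_len(model$n_rules), function(i)
    prod(exp(-(x - model$centers[i, ])^2 / (2 * model$sigmas[i, ]^2))), 0)
  w / sum(w)
}

brute_forward <- function(model, x) {
  wb <- brute_wbar(model, x)
  sum(wb * (as.numeric(model$coeffs %*% x) + model$bias))
}

# Exhaustive best-split oracle: every sign x every midpoint threshold,
# sequential scan respecting the lowest-sign/lowest-threshold tie rule.
brute_best_split <- function(x, y) {
  x <- as.matrix(x); y <- as.character(y)
  n <- nrow(x)
  cnt <- function(lab) c(sum(lab == "benign"), sum(lab == "malignant"))
  g <- function(lab) gini(cnt(lab))
  parent <- g(y)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    uv <- sort(unique(x[, j]))
    if (length(uv) < 2) next
    for (t in (uv[-length(uv)] + uv[-1]) / 2) {
      left <- x[, j] < t
      dec <- parent - (sum(left) * g(y[left]) + sum(!left) * g(y[!left])) / n
      if (dec > 1e-12 &&
          (is.null(best) || dec > best$impurity_decrease + 1e-12))
        best <- list(sign = j, threshold = t, impurity_decrease = dec)
    }
  }
  best
}

# walk a guideline tree collecting its leaves
tree_leaves <- function(node) {
  if (node$leaf) return(list(node))
  c(tree_leaves(node$left), tree_leaves(node$right))
}

# the 1-input, 2-rule generating model of the parameter-recovery benchmark
recovery_problem <- function(n = 200, seed = 42) {
  true <- anfis_model(centers = matrix(c(0.25, 0.75), 2, 1),
                      sigmas = matrix(c(0.15, 0.2), 2, 1),
                      coeffs = matrix(c(2, -1), 2, 1), bias = c(0, 1))
  set.seed(seed)
  x <- matrix(runif(n), n, 1)
  list(model = true, x = x, y = anfis_forward(true, x))
}

sign_cols <- paste0("P", 1:27)
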