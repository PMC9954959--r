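#' Fuzzy c-means clustering
#'
#' Bezdek's fuzzy c-means: alternating updates of cluster centers (fuzzily
#' weighted means) and of the fuzzy partition matrix, minimizing the
#' objective `sum_k sum_i u_ki^m ||x_k - c_i||^2`. The initial partition is
#' drawn from seeded uniform randoms normalized row-wise, so runs are
#' reproducible; the objective is recorded every iteration and is
#' non-increasing by construction of the alternating updates.
#'
#' Used here to place the initial ANFIS rules: each cluster becomes one rule,
#' with the cluster center as premise centers and the fuzzily weighted
#' within-cluster spread as premise sigmas (see [anfis_init()]).
#'
#' @param x numeric `n x d` data matrix.
#' @param n_clusters number of clusters (>= 1, <= n).
#' @param m fuzzifier, > 1; 2 is the standard default.
#' @param tol stop when the objective decreases by less than this.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initial partition.
#' @return An object of class `"fcm"`: list with `centers`
#'   (`n_clusters x d`), `memberships` (`n x n_clusters`, rows sum to 1) and
#'   `objective_trace`.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 1, 0.05), 20))
#' f <- fcm(x, 2, seed = 7)
#' f$centers
#' @export
fcm <- function(x, n_clusters, m = 2, tol = 1e-5, max_iter = 200, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(n_clusters >= 1, n >= n_clusters, m > 1)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  u <- matrix(stats::runif(n * n_clusters), n, n_clusters)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  u <- u / rowSums(u)

  trace <- numeric(0)
  j_prev <- Inf
  for (iter in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    # squared distances n x c, zeros jittered so the update is defined
    d2 <- outer(rowSums(x^2), rep(1, n_clusters)) -
      2 * x %*% t(centers) + outer(rep(1, n), rowSums(centers^2))
    d2[d2 < 1e-12] <- 1e-12
    if (n_clusters == 1L) {
      u <- matrix(1, n, 1)
    } else {
      inv <- d2^(-1 / (m - 1))
      u <- inv / rowSums(inv)
    }
    j <- sum(u^m * d2)
    trace <- c(trace, j)
    if (j_prev - j < tol) break
    j_prev <- j
  }
  structure(list(centers = centers, memberships = u,
                 objective_trace = trace, m = m),
            class = "fcm")
}

#' Initialize an ANFIS model from fuzzy c-means clusters
#'
#' Builds the starting point that all trainers refine. The inputs are min-max
#' scaled to `[0, 1]` per dimension (training-set extrema, stored in the
#' model); FCM with `n_rules` clusters is run on the scaled inputs; rule `i`
#' takes the cluster-`i` center as its premise centers and the fuzzily
#' weighted spread
#' `sigma_ij = sqrt(sum_k u_ki^m (x_kj - c_ij)^2 / sum_k u_ki^m)`
#' (clamped to the spread floor) as its premise sigmas. The consequents are
#' then set by the global ridge least-squares solve shared with the hybrid
#' trainer, so the starting model is already consequent-optimal given its
#' premises.
#'
#' @param x raw input matrix or data frame (numeric sign columns).
#' @param y numeric 0/1 targets (benign = 0, malignant = 1) or a factor with
#'   levels benign/malignant.
#' @param n_rules number of fuzzy rules (default 10).
#' @param m,tol,max_iter,seed passed to [fcm()].
#' @return An `"anfis"` model with stored input scaling.
#' @export
anfis_init <- function(x, y, n_rules = 10, m = 2, tol = 1e-5,
                       max_iter = 200, seed = 1) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_targets(y)
  scaling <- list(min = apply(x, 2, min), max = apply(x, 2, max))
  tmp <- anfis_model(matrix(0, n_rules, ncol(x)), matrix(1, n_rules, ncol(x)),
                     matrix(0, n_rules, ncol(x)), numeric(n_rules),
                     scaling = scaling)
  xs <- scale_inputs(tmp, x)

  f <- fcm(xs, n_rules, m = m, tol = tol, max_iter = max_iter, seed = seed)
  um <- f$memberships^m
  sig <- matrix(0, n_rules, ncol(xs))
  for (i in seq_len(n_rules)) {
    dev2 <- sweep(xs, 2, f$centers[i, ])^2
    sig[i, ] <- sqrt(colSums(um[, i] * dev2) / sum(um[, i]))
  }
  model <- anfis_model(f$centers, pmax(sig, SIGMA_FLOOR),
                       matrix(0, n_rules, ncol(xs)), numeric(n_rules),
                       scaling = scaling)
  set_consequents_ls(model, xs, y)
}

# Coerce benign/malignant labels (factor or character) or numeric targets to
# the 0/1 coding used for training.
as_targets <- function(y) {
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("benign", "malignant"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    as.numeric(y == "malignant")
  } else {
    as.numeric(y)
  }
}
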