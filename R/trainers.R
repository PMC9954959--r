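#' Root mean square error
#'
#' The training fitness of every trainer: `sqrt(mean((predicted - actual)^2))`.
#' Computed on the continuous model output against the 0/1 class targets,
#' regression-style, not on thresholded labels.
#'
#' @param predicted,actual equal-length numeric vectors.
#' @return Non-negative scalar; 0 iff the vectors are identical.
#' @export
rmse <- function(predicted, actual) {
  if (length(predicted) == 0L || length(predicted) != length(actual))
    stop("predicted and actual must be non-empty vectors of equal length")
  sqrt(mean((predicted - actual)^2))
}

#' Genetic-algorithm trainer configuration
#'
#' Defaults are the study settings: 100 iterations, population 50, crossover
#' rate 0.4, mutation rate 0.15, one elite.
#'
#' @param n_iterations generations to run (the only stopping criterion).
#' @param population_size chromosomes per generation (>= 2).
#' @param crossover_rate probability a selected parent pair undergoes
#'   whole-arithmetic crossover (otherwise the parents are copied).
#' @param mutation_rate per-gene probability of Gaussian mutation.
#' @param elitism number of best chromosomes copied unchanged.
#' @param seed integer seed.
#' @return A `"ga_config"` list.
#' @export
ga_config <- function(n_iterations = 100, population_size = 50,
                      crossover_rate = 0.4, mutation_rate = 0.15,
                      elitism = 1, seed = 1) {
  stopifnot(population_size >= 2, n_iterations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0, elitism < population_size)
  structure(list(n_iterations = n_iterations,
                 population_size = population_size,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = elitism, seed = seed),
            class = "ga_config")
}

#' Backpropagation / hybrid trainer configuration
#'
#' Defaults are the study settings: learning rate 0.2, momentum 0.4,
#' 100 iterations.
#'
#' @param learning_rate gradient step size, > 0.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param n_iterations full-batch epochs.
#' @return A `"bp_config"` list.
#' @export
bp_config <- function(learning_rate = 0.2, momentum = 0.4,
                      n_iterations = 100) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            n_iterations >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 n_iterations = n_iterations),
            class = "bp_config")
}

train_result <- function(model, trace, trainer) {
  structure(list(model = model, fitness_trace = trace,
                 final_rmse = trace[length(trace)], trainer = trainer),
            class = "anfis_train")
}

#' @export
print.anfis_train <- function(x, ...) {
  cat(sprintf("ANFIS trained by %s: %d iterations, final RMSE %.5f\n",
              toupper(x$trainer), length(x$fitness_trace), x$final_rmse))
  invisible(x)
}

# Design matrix of the consequent least-squares problem: row k is the
# concatenation over rules i of wbar_ik * [x_k, 1].
consequent_design <- function(model, x) {
  wbar <- firing_strengths(model, x)
  if (!is.matrix(wbar)) wbar <- matrix(wbar, nrow = 1)
  x1 <- cbind(x, 1)
  do.call(cbind, lapply(seq_len(model$n_rules),
                        function(i) wbar[, i] * x1))
}

# Exact (ridge, lambda = 1e-8) least-squares solve of all consequent
# parameters with premises fixed; shared by anfis_init and train_hybrid.
set_consequents_ls <- function(model, x, y, lambda = 1e-8) {
  a <- consequent_design(model, x)
  ata <- crossprod(a) + diag(lambda, ncol(a))
  theta <- solve(ata, crossprod(a, y))
  cons <- matrix(theta, model$n_rules, model$n_inputs + 1, byrow = TRUE)
  anfis_model(model$centers, model$sigmas,
              cons[, seq_len(model$n_inputs), drop = FALSE],
              cons[, model$n_inputs + 1], scaling = model$scaling)
}

#' Analytic RMSE gradient of an ANFIS model
#'
#' Gradient of the training RMSE with respect to every free parameter, in the
#' [anfis_encode()] layout, derived through the five network layers:
#' with residuals `e_k = yhat_k - y_k` and normalized strengths `wbar`,
#' `d yhat / d r_i = wbar_i`, `d yhat / d p_ij = wbar_i x_j`,
#' `d yhat / d c_ij = wbar_i (f_i - yhat) (x_j - c_ij) / sigma_ij^2` and
#' `d yhat / d sigma_ij = wbar_i (f_i - yhat) (x_j - c_ij)^2 / sigma_ij^3`.
#'
#' @param model an `"anfis"` model.
#' @param x `n x n_inputs` matrix in the model's input space.
#' @param y numeric targets.
#' @return Numeric gradient vector of length `parameter_count(...)`.
#' @keywords internal
anfis_gradient <- function(model, x, y) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  n <- nrow(x); d <- model$n_inputs; r <- model$n_rules
  wbar <- firing_strengths(model, x)
  if (!is.matrix(wbar)) wbar <- matrix(wbar, nrow = 1)
  f <- x %*% t(model$coeffs) + matrix(model$bias, n, r, byrow = TRUE)
  yhat <- rowSums(wbar * f)
  e <- yhat - y
  rmse_val <- sqrt(mean(e^2))
  if (rmse_val == 0) return(numeric(parameter_count(d, r)))
  # dE/d theta = (1 / (n * RMSE)) * sum_k e_k * d yhat_k / d theta
  scl <- e / (n * rmse_val)

  gc_ <- matrix(0, r, d); gs <- matrix(0, r, d)
  gp <- matrix(0, r, d); gr <- numeric(r)
  for (i in seq_len(r)) {
    common <- scl * wbar[, i] * (f[, i] - yhat)        # n-vector
    dx <- sweep(x, 2, model$centers[i, ])              # x - c_i
    s2 <- model$sigmas[i, ]^2
    gc_[i, ] <- colSums(common * sweep(dx, 2, s2, "/"))
    gs[i, ] <- colSums(common * sweep(dx^2, 2, model$sigmas[i, ]^3, "/"))
    gp[i, ] <- colSums((scl * wbar[, i]) * x)
    gr[i] <- sum(scl * wbar[, i])
  }
  prem <- as.numeric(rbind(as.numeric(t(gc_)), as.numeric(t(gs))))
  cons <- as.numeric(t(cbind(gp, gr)))
  c(prem, cons)
}

#' Train ANFIS by backpropagation with momentum
#'
#' Full-batch gradient descent on the training RMSE over all parameters
#' (premise centers and spreads and the consequents), with the classical
#' momentum update `v <- momentum * v - lr * grad; theta <- theta + v`.
#' Spread genes are clamped on decode, so the model stays valid throughout.
#'
#' @param x input matrix in the model's (scaled) input space.
#' @param y numeric 0/1 targets.
#' @param model the initialized template model (normally from [anfis_init()]).
#' @param config a [bp_config()].
#' @return An `"anfis_train"` result: trained model, per-epoch RMSE trace and
#'   final RMSE.
#' @export
train_bp <- function(x, y, model, config = bp_config()) {
  x <- as.matrix(x); y <- as_targets(y)
  theta <- anfis_encode(model)
  v <- numeric(length(theta))
  trace <- numeric(config$n_iterations)
  cur <- model
  for (it in seq_len(config$n_iterations)) {
    g <- anfis_gradient(cur, x, y)
    v <- config$momentum * v - config$learning_rate * g
    theta <- theta + v
    cur <- anfis_decode(theta, model)
    trace[it] <- rmse(anfis_forward(cur, x), y)
    if (!is.finite(trace[it]) || trace[it] > 1e6)
      stop("backpropagation diverged (RMSE > 1e6); reduce the learning rate")
  }
  train_result(cur, trace, "bp")
}

#' Train ANFIS by hybrid least-squares / backpropagation
#'
#' Each epoch first solves all consequent parameters exactly by (ridge)
#' linear least squares with the premises held fixed, then takes one
#' momentum backpropagation step on the premise parameters only. After every
#' least-squares pass the consequents are optimal for the current premises.
#'
#' @inheritParams train_bp
#' @return An `"anfis_train"` result.
#' @export
train_hybrid <- function(x, y, model, config = bp_config()) {
  x <- as.matrix(x); y <- as_targets(y)
  d <- model$n_inputs; r <- model$n_rules
  n_prem <- 2 * d * r
  cur <- model
  v <- numeric(n_prem)
  trace <- numeric(config$n_iterations)
  for (it in seq_len(config$n_iterations)) {
    cur <- set_consequents_ls(cur, x, y)
    g <- anfis_gradient(cur, x, y)[seq_len(n_prem)]
    v <- config$momentum * v - config$learning_rate * g
    theta <- anfis_encode(cur)
    theta[seq_len(n_prem)] <- theta[seq_len(n_prem)] + v
    cur <- anfis_decode(theta, model)
    trace[it] <- rmse(anfis_forward(cur, x), y)
    if (!is.finite(trace[it]) || trace[it] > 1e6)
      stop("hybrid training diverged (RMSE > 1e6); reduce the learning rate")
  }
  # final LS polish so the returned model is consequent-optimal
  cur <- set_consequents_ls(cur, x, y)
  trace[config$n_iterations] <- rmse(anfis_forward(cur, x), y)
  train_result(cur, trace, "hybrid")
}

#' Train ANFIS by a real-coded genetic algorithm
#'
#' The flat parameter vector of the model is the chromosome; fitness is the
#' training RMSE of the decoded model. Each generation: the best `elitism`
#' chromosomes are carried over unchanged; parents are picked by
#' tournament-2 selection; with probability `crossover_rate` a parent pair
#' produces whole-arithmetic children `beta * p1 + (1 - beta) * p2` and its
#' complement (`beta ~ U(0, 1)`), otherwise the parents are copied; every
#' gene then mutates with probability `mutation_rate` by a Gaussian
#' perturbation with sd equal to 10% of that gene's range, clipped to the
#' gene bounds. The initial population is the encoded template plus
#' mutation-scale Gaussian perturbations of it. Runs are deterministic for a
#' fixed `config$seed`, and elitism makes the best-fitness trace
#' non-increasing.
#'
#' @inheritParams train_bp
#' @param config a [ga_config()].
#' @return An `"anfis_train"` result; `fitness_trace` holds the best RMSE of
#'   each generation.
#' @export
train_ga <- function(x, y, model, config = ga_config()) {
  x <- as.matrix(x); y <- as_targets(y)
  d <- model$n_inputs; r <- model$n_rules
  b <- gene_bounds(d, r)
  rng <- b$upper - b$lower
  np <- config$population_size
  nl <- parameter_count(d, r)

  set.seed(config$seed)
  # the initialized template enters the population unclipped (elitism must be
  # able to preserve the consequent-optimal start); bounds constrain the
  # offspring of crossover and mutation
  template <- anfis_encode(model)
  pop <- matrix(template, nl, np)
  if (np > 1) {
    noise <- matrix(stats::rnorm(nl * (np - 1), sd = 0.1 * rng), nl, np - 1)
    pop[, -1] <- pop[, -1] + noise
  }

  fit_one <- function(genes)
    rmse(anfis_forward(anfis_decode(genes, model), x), y)
  fitness <- apply(pop, 2, fit_one)

  trace <- numeric(config$n_iterations)
  for (gen in seq_len(config$n_iterations)) {
    ord <- order(fitness)
    elite <- pop[, ord[seq_len(config$elitism)], drop = FALSE]

    # tournament-2 parent selection
    pick <- function() {
      a <- sample.int(np, 2)
      if (fitness[a[1]] <= fitness[a[2]]) a[1] else a[2]
    }
    n_child <- np - config$elitism
    children <- matrix(0, nl, n_child)
    ci <- 1
    while (ci <= n_child) {
      p1 <- pop[, pick()]; p2 <- pop[, pick()]
      if (stats::runif(1) < config$crossover_rate) {
        beta <- stats::runif(1)
        c1 <- beta * p1 + (1 - beta) * p2
        c2 <- (1 - beta) * p1 + beta * p2
      } else {
        c1 <- p1; c2 <- p2
      }
      children[, ci] <- c1
      if (ci + 1 <= n_child) children[, ci + 1] <- c2
      ci <- ci + 2
    }
    # per-gene Gaussian mutation, sd = 10% of the gene range, clipped
    mut <- matrix(stats::runif(nl * n_child) < config$mutation_rate,
                  nl, n_child)
    if (any(mut)) {
      pert <- matrix(stats::rnorm(nl * n_child, sd = 0.1 * rng), nl, n_child)
      children <- children + mut * pert
    }
    children <- pmin(pmax(children, b$lower), b$upper)

    pop <- cbind(elite, children)
    fitness <- c(fitness[ord[seq_len(config$elitism)]],
                 apply(children, 2, fit_one))
    trace[gen] <- min(fitness)
  }
  best <- pop[, which.min(fitness)]
  train_result(anfis_decode(best, model), trace, "ga")
}

#' Fit an ANFIS nodule classifier end to end
#'
#' Convenience wrapper running the full pipeline on a raw sign table:
#' min-max scaling from the training extrema, fuzzy c-means rule
#' initialization, consequent least squares, then the chosen trainer. The
#' returned model carries the scaling, so [predict.anfis()] can be applied
#' directly to raw test tables.
#'
#' @param x data frame or matrix of sign columns (raw codes).
#' @param y labels: benign/malignant factor or 0/1 numeric.
#' @param trainer `"ga"`, `"bp"` or `"hybrid"`.
#' @param n_rules number of fuzzy rules (default 10).
#' @param config a [ga_config()] or [bp_config()] matching the trainer;
#'   defaults to the study settings.
#' @param seed seed for the FCM initialization (and the GA when `config` is
#'   left `NULL`).
#' @return An `"anfis_train"` result.
#' @examples
#' tbl <- generate_nodules(n_total = 120, n_malignant = 80, seed = 3)
#' fit <- anfis_fit(tbl[paste0("P", 1:27)], tbl$label, trainer = "hybrid",
#'                  config = bp_config(n_iterations = 10))
#' table(predict(fit$model, tbl[paste0("P", 1:27)], type = "class"), tbl$label)
#' @export
anfis_fit <- function(x, y, trainer = c("ga", "bp", "hybrid"), n_rules = 10,
                      config = NULL, seed = 1) {
  trainer <- match.arg(trainer)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_targets(y)
  model <- anfis_init(x, y, n_rules = n_rules, seed = seed)
  xs <- scale_inputs(model, x)
  if (is.null(config))
    config <- if (trainer == "ga") ga_config(seed = seed) else bp_config()
  switch(trainer,
         ga = train_ga(xs, y, model, config),
         bp = train_bp(xs, y, model, config),
         hybrid = train_hybrid(xs, y, model, config))
}
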