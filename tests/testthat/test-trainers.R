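test_that("rmse follows its closed form", {
  expect_identical(rmse(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_identical(rmse(1, 0), 1)
  expect_identical(rmse(c(3, -1), c(1, 1)), 2)  # sqrt((4 + 4) / 2)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:2), "equal length")
})

test_that("GA preserves an already-optimal template and never regresses", {
  prob <- recovery_problem(n = 60)
  # targets generated exactly by the template: fitness starts and stays 0
  r <- train_ga(prob$x, prob$y, prob$model,
                ga_config(n_iterations = 15, population_size = 12, seed = 2))
  expect_equal(r$fitness_trace, rep(0, 15), tolerance = 1e-12)

  init <- anfis_init(prob$x, prob$y, n_rules = 2, seed = 5)
  xs <- anfiscad:::scale_inputs(init, prob$x)
  r2 <- train_ga(xs, prob$y, init,
                 ga_config(n_iterations = 25, population_size = 16, seed = 3))
  expect_true(all(diff(r2$fitness_trace) <= 1e-12))
  expect_identical(r2$final_rmse, r2$fitness_trace[length(r2$fitness_trace)])
})

test_that("GA runs are deterministic in the seed", {
  prob <- recovery_problem(n = 80)
  init <- anfis_init(prob$x, prob$y, n_rules = 2, seed = 5)
  xs <- anfiscad:::scale_inputs(init, prob$x)
  cfg <- ga_config(n_iterations = 10, population_size = 10, seed = 21)
  a <- train_ga(xs, prob$y, init, cfg)
  b <- train_ga(xs, prob$y, init, cfg)
  expect_identical(a$fitness_trace, b$fitness_trace)
  expect_identical(anfis_encode(a$model), anfis_encode(b$model))
  c_ <- train_ga(xs, prob$y, init,
                 ga_config(n_iterations = 10, population_size = 10, seed = 22))
  expect_false(identical(a$fitness_trace, c_$fitness_trace))
})

test_that("a zero learning rate leaves the model untouched", {
  prob <- recovery_problem(n = 50)
  init <- anfis_init(prob$x, prob$y, n_rules = 2, seed = 5)
  xs <- anfiscad:::scale_inputs(init, prob$x)
  r <- train_bp(xs, prob$y, init,
                bp_config(learning_rate = 0, n_iterations = 8))
  expect_identical(anfis_encode(r$model), anfis_encode(init))
  expect_length(unique(r$fitness_trace), 1L)
})

test_that("analytic gradients match central finite differences", {
  m <- rand_model(2, 3, seed = 3)
  set.seed(4)
  x <- matrix(runif(30), 15, 2)
  y <- rnorm(15)
  g <- anfiscad:::anfis_gradient(m, x, y)
  th <- anfis_encode(m)
  h <- 1e-6
  fd <- vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + h
    tm <- th; tm[i] <- tm[i] - h
    (rmse(anfis_forward(anfis_decode(tp, m), x), y) -
       rmse(anfis_forward(anfis_decode(tm, m), x), y)) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-5)
})

test_that("backpropagation solves the convex consequent problem", {
  set.seed(7)
  x <- matrix(runif(60), 30, 2)
  y <- as.numeric(x %*% c(0.8, -0.4) + 0.3)
  tmpl <- anfis_model(matrix(0.5, 1, 2), matrix(0.3, 1, 2),
                      matrix(0, 1, 2), 0)
  # closed-form least squares is exact here; BP should approach it
  ls <- anfiscad:::set_consequents_ls(tmpl, x, y)
  expect_equal(rmse(anfis_forward(ls, x), y), 0, tolerance = 1e-6)
  r <- train_bp(x, y, tmpl,
                bp_config(learning_rate = 0.02, n_iterations = 300))
  expect_lt(r$final_rmse, 0.05)
})

test_that("the hybrid LS step is the exact minimizer over consequents", {
  set.seed(12)
  for (rep in 1:3) {
    r <- sample(2:3, 1)
    x <- matrix(runif(2 * 15), 15, 2)
    y <- rnorm(15)
    m <- rand_model(2, r, seed = 40 + rep)
    ls <- anfiscad:::set_consequents_ls(m, x, y)
    ls_rmse <- rmse(anfis_forward(ls, x), y)
    # brute-force numeric minimization over all consequent parameters
    obj <- function(v) {
      mm <- ls
      cons <- matrix(v, r, 3, byrow = TRUE)
      mm$coeffs <- cons[, 1:2, drop = FALSE]
      mm$bias <- cons[, 3]
      rmse(anfis_forward(mm, x), y)
    }
    v0 <- as.numeric(t(cbind(ls$coeffs, ls$bias)))
    opt <- stats::optim(v0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    expect_lte(ls_rmse, opt$value + 1e-6)
  }

  # single-rule exact linear data: RMSE 0 from the very first LS pass
  set.seed(13)
  x <- matrix(runif(40), 20, 2)
  y <- as.numeric(x %*% c(1, 2) - 0.5)
  tmpl <- anfis_model(matrix(0.5, 1, 2), matrix(0.25, 1, 2),
                      matrix(0, 1, 2), 0)
  r1 <- train_hybrid(x, y, tmpl, bp_config(n_iterations = 2))
  expect_equal(r1$final_rmse, 0, tolerance = 1e-6)
})

test_that("hybrid training beats plain backpropagation on the recovery task", {
  prob <- recovery_problem()
  init <- anfis_init(prob$x, prob$y, n_rules = 2, seed = 5)
  xs <- anfiscad:::scale_inputs(init, prob$x)
  hb <- train_hybrid(xs, prob$y, init, bp_config())
  bp <- train_bp(xs, prob$y, init, bp_config())
  expect_lte(hb$final_rmse, bp$final_rmse)
})
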