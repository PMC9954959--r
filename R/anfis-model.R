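# Premise spreads are clamped to this floor (on the scaled [0,1] input axis)
# so memberships never degenerate to a point mass and rule normalization never
# divides by zero.
SIGMA_FLOOR <- 1e-3

#' First-order Takagi--Sugeno ANFIS model
#'
#' Constructs an ANFIS model with Gaussian rule premises and linear (first
#' order Sugeno) consequents. Each of the `n_rules` rules owns one Gaussian
#' membership function per input dimension (a cluster-style rule base, as
#' produced by fuzzy c-means initialization), a vector of consequent
#' coefficients and a consequent bias. The model output for an input vector
#' `x` is the normalized-firing-strength-weighted sum of the rule outputs
#' `p_i . x + r_i`.
#'
#' @param centers `n_rules x n_inputs` matrix of Gaussian membership centers.
#' @param sigmas  `n_rules x n_inputs` matrix of Gaussian spreads; values
#'   below the spread floor (`1e-3`) are clamped up to it.
#' @param coeffs  `n_rules x n_inputs` matrix of consequent coefficients
#'   (the `p` parameters, one row per rule).
#' @param bias    length-`n_rules` vector of consequent bias terms (the `r`
#'   parameters).
#' @param scaling optional per-dimension input scaling, a list with numeric
#'   vectors `min` and `max` (length `n_inputs`) mapping raw inputs onto
#'   `[0, 1]` via `(x - min) / (max - min)`. `NULL` means inputs are used
#'   as-is. The scaling learned from a training table travels with the model
#'   so test data are mapped identically.
#'
#' @return An object of class `"anfis"`.
#' @examples
#' m <- anfis_model(centers = matrix(0.5, 1, 2), sigmas = matrix(0.2, 1, 2),
#'                  coeffs = matrix(c(1, -1), 1, 2), bias = 0.5)
#' anfis_forward(m, c(0.3, 0.6))
#' @seealso [anfis_fit()] for the full scale/initialize/train pipeline,
#'   [anfis_forward()], [predict.anfis()], [anfis_encode()].
#' @export
anfis_model <- function(centers, sigmas, coeffs, bias, scaling = NULL) {
  centers <- as.matrix(centers)
  sigmas <- as.matrix(sigmas)
  coeffs <- as.matrix(coeffs)
  bias <- as.numeric(bias)
  if (!all(dim(sigmas) == dim(centers)) || !all(dim(coeffs) == dim(centers)))
    stop("centers, sigmas and coeffs must share dimensions n_rules x n_inputs")
  if (length(bias) != nrow(centers))
    stop("bias must have one entry per rule")
  if (any(!is.finite(centers)) || any(!is.finite(sigmas)) ||
      any(!is.finite(coeffs)) || any(!is.finite(bias)))
    stop("ANFIS parameters must be finite")
  sigmas <- pmax(sigmas, SIGMA_FLOOR)
  if (!is.null(scaling)) {
    stopifnot(is.list(scaling), length(scaling$min) == ncol(centers),
              length(scaling$max) == ncol(centers))
    if (any(scaling$max < scaling$min))
      stop("scaling max must be >= min in every dimension")
  }
  structure(
    list(n_inputs = ncol(centers), n_rules = nrow(centers),
         centers = centers, sigmas = sigmas,
         coeffs = coeffs, bias = bias, scaling = scaling),
    class = "anfis"
  )
}

#' @export
print.anfis <- function(x, ...) {
  cat(sprintf(
    "Takagi-Sugeno ANFIS: %d inputs, %d rules, %d free parameters%s\n",
    x$n_inputs, x$n_rules, parameter_count(x$n_inputs, x$n_rules),
    if (is.null(x$scaling)) "" else " (with stored input scaling)"))
  invisible(x)
}

#' Gaussian membership value
#'
#' Evaluates the Gaussian membership function
#' `exp(-(x - center)^2 / (2 * sigma^2))`. Vectorized over `x`.
#'
#' @param x numeric input(s).
#' @param center membership center.
#' @param sigma spread, must be strictly positive.
#' @return Membership values in `(0, 1]`; exactly 1 at `x == center`.
#' @examples
#' gauss_mf(0.5, center = 0.5, sigma = 0.1)  # 1
#' gauss_mf(1, 0, 1)                         # exp(-0.5)
#' @export
gauss_mf <- function(x, center, sigma) {
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  exp(-((x - center)^2) / (2 * sigma^2))
}

# Map raw inputs through the model's stored min-max scaling (identity when
# the model carries none). Degenerate dimensions (max == min) map to 0.5.
scale_inputs <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (is.null(model$scaling)) return(x)
  rng <- model$scaling$max - model$scaling$min
  rng[rng == 0] <- 1
  sc <- sweep(sweep(x, 2, model$scaling$min), 2, rng, "/")
  deg <- model$scaling$max == model$scaling$min
  if (any(deg)) sc[, deg] <- 0.5
  sc
}

# Row-wise log raw firing strengths, n x n_rules. x must already be in the
# model's (scaled) input space.
log_firing <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(x) != model$n_inputs)
    stop(sprintf("expected %d inputs, got %d", model$n_inputs, ncol(x)))
  out <- matrix(0, nrow(x), model$n_rules)
  for (i in seq_len(model$n_rules)) {
    z <- sweep(x, 2, model$centers[i, ])
    z <- sweep(z, 2, model$sigmas[i, ], "/")
    out[, i] <- -0.5 * rowSums(z^2)
  }
  out
}

#' Normalized rule firing strengths
#'
#' Layer 2 and 3 of the ANFIS network: the raw firing strength of rule `i` at
#' input `x` is the product over input dimensions of its Gaussian membership
#' values; the normalized strengths divide each raw strength by their sum.
#' Products are accumulated in log space and shifted by the row maximum before
#' exponentiation, so normalization is well defined even when every raw
#' strength underflows.
#'
#' @param model an [anfis_model()].
#' @param x numeric vector of length `n_inputs`, or an `n x n_inputs` matrix,
#'   already in the model's input space (no raw-data scaling is applied here).
#' @return For a vector input, a length-`n_rules` vector summing to 1; for a
#'   matrix, an `n x n_rules` matrix with unit row sums.
#' @export
firing_strengths <- function(model, x) {
  lw <- log_firing(model, x)
  w <- exp(lw - apply(lw, 1, max))
  w <- w / rowSums(w)
  if (!is.matrix(x)) drop(w) else w
}

#' ANFIS forward pass
#'
#' Full five-layer evaluation: memberships, rule products, normalization,
#' weighted linear consequents, and the output sum
#' `sum_i wbar_i * (p_i . x + r_i)`. The result is a continuous score, not a
#' class label; see [anfis_classify()] for thresholding.
#'
#' @inheritParams firing_strengths
#' @return Numeric score(s), one per input row.
#' @export
anfis_forward <- function(model, x) {
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  wbar <- firing_strengths(model, x)
  if (!is.matrix(wbar)) wbar <- matrix(wbar, nrow = 1)
  f <- x %*% t(model$coeffs) + matrix(model$bias, nrow(x), model$n_rules,
                                      byrow = TRUE)
  drop(rowSums(wbar * f))
}

#' Number of free ANFIS parameters
#'
#' Each rule carries one Gaussian membership function (center + spread) per
#' input plus a first-order consequent (`n_inputs` coefficients and a bias):
#' `2 * n_inputs * n_rules + (n_inputs + 1) * n_rules` in total. With the
#' default 10 rules this gives 820, 400 and 250 parameters for 27, 13 and 8
#' inputs respectively.
#'
#' @param n_inputs,n_rules positive integers.
#' @return Integer parameter count.
#' @examples
#' parameter_count(27, 10)  # 820
#' @export
parameter_count <- function(n_inputs, n_rules) {
  stopifnot(n_inputs >= 1, n_rules >= 1)
  as.integer(2 * n_inputs * n_rules + (n_inputs + 1) * n_rules)
}

#' Flat parameter encoding (the GA chromosome)
#'
#' `anfis_encode()` flattens all premise and consequent parameters into a
#' single numeric vector: first all `(center, sigma)` pairs, rule-major then
#' input-major, then all consequent blocks `(p_1..p_d, r)` rule by rule.
#' `anfis_decode()` inverts the map, taking the shape (and input scaling)
#' from a template model; spread genes are clamped to the spread floor so any
#' real vector decodes to a valid model.
#'
#' @param model,template an [anfis_model()]; `template` supplies the shape
#'   and scaling during decoding.
#' @param values numeric vector of length `parameter_count(n_inputs, n_rules)`.
#' @return `anfis_encode()` a numeric vector; `anfis_decode()` an `"anfis"`
#'   model.
#' @export
anfis_encode <- function(model) {
  stopifnot(inherits(model, "anfis"))
  prem <- as.numeric(rbind(as.numeric(t(model$centers)),
                           as.numeric(t(model$sigmas))))
  cons <- as.numeric(t(cbind(model$coeffs, model$bias)))
  c(prem, cons)
}

#' @rdname anfis_encode
#' @export
anfis_decode <- function(values, template) {
  stopifnot(inherits(template, "anfis"))
  d <- template$n_inputs; r <- template$n_rules
  expect <- parameter_count(d, r)
  if (length(values) != expect)
    stop(sprintf("parameter vector has length %d, model shape needs %d",
                 length(values), expect))
  prem <- matrix(values[seq_len(2 * d * r)], ncol = 2, byrow = TRUE)
  centers <- matrix(prem[, 1], r, d, byrow = TRUE)
  sigmas <- matrix(prem[, 2], r, d, byrow = TRUE)
  cons <- matrix(values[-seq_len(2 * d * r)], r, d + 1, byrow = TRUE)
  anfis_model(centers, pmax(sigmas, SIGMA_FLOOR),
              cons[, seq_len(d), drop = FALSE], cons[, d + 1],
              scaling = template$scaling)
}

# Gene-wise lower/upper bounds in encode order: centers span the scaled input
# range with margin, spreads live in [floor, 2], consequents in [-10, 10].
gene_bounds <- function(n_inputs, n_rules) {
  prem_lo <- rep(c(-0.25, SIGMA_FLOOR), n_inputs * n_rules)
  prem_hi <- rep(c(1.25, 2), n_inputs * n_rules)
  cons_lo <- rep(rep(-10, n_inputs + 1), n_rules)
  cons_hi <- rep(rep(10, n_inputs + 1), n_rules)
  list(lower = c(prem_lo, cons_lo), upper = c(prem_hi, cons_hi))
}

#' Classify nodules with a trained ANFIS model
#'
#' Thresholds the continuous forward score under the benign = 0 /
#' malignant = 1 target coding: a nodule is called malignant when its score is
#' at least 0.5. The boundary case goes to malignant — the conservative call
#' for a cancer screen.
#'
#' @param model a trained [anfis_model()].
#' @param x raw input vector or matrix; the model's stored input scaling is
#'   applied before evaluation.
#' @return Factor with levels `benign`, `malignant`.
#' @export
anfis_classify <- function(model, x) {
  score <- anfis_forward(model, scale_inputs(model, x))
  factor(ifelse(score >= 0.5, "malignant", "benign"),
         levels = c("benign", "malignant"))
}

#' Predict method for ANFIS models
#'
#' @param object an `"anfis"` model.
#' @param newdata data frame or matrix of raw inputs (sign columns only, in
#'   the order the model was fitted with).
#' @param type `"score"` for the continuous output, `"class"` for the
#'   thresholded benign/malignant factor.
#' @param ... unused.
#' @return Numeric scores or a factor, one per row.
#' @export
predict.anfis <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (type == "class") return(anfis_classify(object, x))
  anfis_forward(object, scale_inputs(object, x))
}

#' Serialize an ANFIS model to JSON
#'
#' Writes (and reads back) the model as a flat JSON document holding the
#' shape, the input-scaling pairs and the encoded parameter vector at full
#' double precision, so a round trip reproduces the model exactly.
#'
#' @param model an `"anfis"` model.
#' @param path file path.
#' @return `write_anfis()` returns `path` invisibly; `read_anfis()` returns
#'   the model.
#' @export
write_anfis <- function(model, path) {
  stopifnot(inherits(model, "anfis"))
  # doubles go through 17-significant-digit decimal strings, which round-trip
  # IEEE doubles exactly
  num17 <- function(v) sprintf("%.17g", v)
  doc <- list(
    format = "anfiscad-model-1",
    n_inputs = model$n_inputs, n_rules = model$n_rules,
    layout = "premise (center,sigma) rule-major input-major; consequent (p,r) rule-major",
    scaling = if (is.null(model$scaling)) NULL else
      list(min = num17(model$scaling$min), max = num17(model$scaling$max)),
    values = num17(anfis_encode(model))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_anfis
#' @export
read_anfis <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$format) || doc$format != "anfiscad-model-1")
    stop("not an anfiscad model document")
  d <- doc$n_inputs; r <- doc$n_rules
  scaling <- if (is.null(doc$scaling)) NULL else
    list(min = as.numeric(doc$scaling$min), max = as.numeric(doc$scaling$max))
  template <- anfis_model(matrix(0, r, d), matrix(1, r, d),
                          matrix(0, r, d), numeric(r), scaling = scaling)
  anfis_decode(as.numeric(doc$values), template)
}
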