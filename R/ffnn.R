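#' Hyperbolic-tangent sigmoid transfer function
#'
#' The hidden-layer transfer function `tansig(z) = 2 / (1 + exp(-2 z)) - 1`,
#' mapping the reals onto (-1, 1). The output layer is linear.
#'
#' @param z Numeric vector or matrix.
#' @return Same shape as `z`.
#' @examples
#' tansig(c(-1, 0, 1))
#' @export
tansig <- function(z) 2 / (1 + exp(-2 * z)) - 1

#' Random initial parameters for a single-hidden-layer perceptron
#'
#' Draws every weight and bias i.i.d. uniform on `[-0.5, 0.5]`,
#' reproducibly for a given seed. A 6-h-1 network has
#' `6 h + h + h + 1` free parameters (81 for h = 10).
#'
#' @param n_in Number of input nodes (factors), default 6.
#' @param n_hidden Number of hidden nodes.
#' @param seed Integer seed.
#' @return An `ffnn_params` list: `hidden_weights` (`n_hidden x n_in`),
#'   `input_bias` (length `n_hidden`), `output_weights` (length
#'   `n_hidden`), `output_bias` (scalar).
#' @examples
#' p <- init_params(6, 10, seed = 1)
#' @export
init_params <- function(n_in = 6, n_hidden = 10, seed = 1) {
  check_that(n_in >= 1 && n_hidden >= 1, "invalid topology")
  set.seed(seed)
  structure(
    list(
      hidden_weights = matrix(runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
      input_bias = runif(n_hidden, -0.5, 0.5),
      output_weights = runif(n_hidden, -0.5, 0.5),
      output_bias = runif(1, -0.5, 0.5)
    ),
    class = "ffnn_params"
  )
}

n_free_params <- function(params) {
  length(params$hidden_weights) + length(params$input_bias) +
    length(params$output_weights) + 1L
}

pack_params <- function(params) {
  c(as.vector(params$hidden_weights), params$input_bias,
    params$output_weights, params$output_bias)
}

unpack_params <- function(theta, n_in, n_hidden) {
  i1 <- n_hidden * n_in
  structure(
    list(
      hidden_weights = matrix(theta[seq_len(i1)], n_hidden, n_in),
      input_bias = theta[i1 + seq_len(n_hidden)],
      output_weights = theta[i1 + n_hidden + seq_len(n_hidden)],
      output_bias = theta[i1 + 2L * n_hidden + 1L]
    ),
    class = "ffnn_params"
  )
}

#' Forward pass of the perceptron
#'
#' Evaluates `output_weights . tansig(hidden_weights %*% x + input_bias)
#' + output_bias` for one input vector or for each row of a matrix of
#' scaled inputs.
#'
#' @param params An `ffnn_params` list.
#' @param x A numeric vector of length `n_in`, or a matrix with `n_in`
#'   columns (one row per candidate).
#' @return Numeric vector of network outputs (one per row).
#' @examples
#' p <- init_params(2, 3, seed = 1)
#' ffnn_forward(p, c(0.2, -0.4))
#' @export
ffnn_forward <- function(params, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  check_that(ncol(x) == ncol(params$hidden_weights),
             sprintf("input has %d columns but network expects %d",
                     ncol(x), ncol(params$hidden_weights)))
  a <- tansig(sweep(x %*% t(params$hidden_weights), 2, params$input_bias, "+"))
  drop(a %*% params$output_weights) + params$output_bias
}

# Analytic Jacobian of the prediction vector w.r.t. the packed parameters,
# in pack_params() order. A finite-difference version lives in the test
# suite as an oracle.
ffnn_jacobian <- function(params, x) {
  n_hidden <- nrow(params$hidden_weights)
  n_in <- ncol(params$hidden_weights)
  a <- tansig(sweep(x %*% t(params$hidden_weights), 2, params$input_bias, "+"))
  d <- sweep(1 - a^2, 2, params$output_weights, "*")   # n x n_hidden
  j_w <- do.call(cbind, lapply(seq_len(n_in), function(j) d * x[, j]))
  cbind(j_w, d, a, rep(1, nrow(x)))
}

#' Training control for Levenberg-Marquardt
#'
#' Defaults are the standard damped Gauss-Newton settings: initial damping
#' `lambda0 = 1e-3`, multiplied by `factor_up = 10` when a step is rejected
#' and divided by `factor_down = 10` when accepted; training stops at
#' `max_epochs` accepted iterations (default 1000), when the sum of squared
#' errors falls below `sse_tol`, when the gradient's max absolute entry
#' falls below `grad_tol`, or when the damping exceeds `lambda_max` (no
#' further progress possible). `n_restarts` independent random
#' initializations are trained and the lowest-SSE network kept, since a
#' single random start is not reproducible science.
#'
#' @param max_epochs,lambda0,factor_up,factor_down,sse_tol,grad_tol,lambda_max
#'   See description.
#' @param n_restarts Number of random initializations (default 10).
#' @param seed Base seed; restart `i` uses `seed + i - 1`.
#' @return A list of class `lm_control`.
#' @export
lm_control <- function(max_epochs = 1000, lambda0 = 1e-3, factor_up = 10,
                       factor_down = 10, sse_tol = 1e-12, grad_tol = 1e-10,
                       lambda_max = 1e12, n_restarts = 10, seed = 1) {
  check_that(max_epochs >= 1, "`max_epochs` must be >= 1")
  check_that(factor_up > 1 && factor_down > 1, "LM factors must be > 1")
  check_that(n_restarts >= 1, "`n_restarts` must be >= 1")
  structure(list(max_epochs = max_epochs, lambda0 = lambda0,
                 factor_up = factor_up, factor_down = factor_down,
                 sse_tol = sse_tol, grad_tol = grad_tol,
                 lambda_max = lambda_max, n_restarts = n_restarts,
                 seed = seed),
            class = "lm_control")
}

# One LM run from a given initialization. Full-batch damped Gauss-Newton on
# SSE with the analytic Jacobian; accepted steps strictly reduce the SSE.
lm_run <- function(x, y, params, control) {
  n_in <- ncol(params$hidden_weights)
  n_hidden <- nrow(params$hidden_weights)
  theta <- pack_params(params)
  p <- length(theta)
  resid_of <- function(th) ffnn_forward(unpack_params(th, n_in, n_hidden), x) - y

  r <- resid_of(theta)
  sse <- sum(r^2)
  sse_trace <- sse
  lambda <- control$lambda0
  epochs <- 0L
  while (epochs < control$max_epochs && sse > control$sse_tol) {
    jac <- ffnn_jacobian(unpack_params(theta, n_in, n_hidden), x)
    g <- crossprod(jac, r)
    if (max(abs(g)) < control$grad_tol) break
    h <- crossprod(jac)
    accepted <- FALSE
    while (!accepted && lambda <= control$lambda_max) {
      step <- tryCatch(
        solve(h + diag(lambda, p), -g),
        error = function(e) NULL
      )
      if (!is.null(step)) {
        theta_new <- theta + drop(step)
        r_new <- resid_of(theta_new)
        sse_new <- sum(r_new^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- theta_new
          r <- r_new
          sse <- sse_new
          lambda <- lambda / control$factor_down
          sse_trace <- c(sse_trace, sse)
          accepted <- TRUE
        }
      }
      if (!accepted) lambda <- lambda * control$factor_up
    }
    if (!accepted) break   # damping exhausted: local minimum reached
    epochs <- epochs + 1L
  }
  list(params = unpack_params(theta, n_in, n_hidden), sse = sse,
       epochs = epochs, sse_trace = sse_trace)
}

#' Train a perceptron by Levenberg-Marquardt least squares
#'
#' Fits the single-hidden-layer network to scaled data by full-batch
#' damped Gauss-Newton on the sum of squared errors, using the analytic
#' Jacobian. `n_restarts` seeded random initializations are trained and
#' the network with the lowest final SSE is returned.
#'
#' @param x Numeric matrix of scaled inputs (rows = runs, columns =
#'   factors, nominally in `[-1, 1]`).
#' @param y Numeric vector of scaled targets.
#' @param n_hidden Hidden-layer size.
#' @param control An [lm_control()] list.
#' @return An `ffnn_fit`: `params`, `final_sse`, `epochs_run`,
#'   `sse_trace` (SSE after initialization and after each accepted step),
#'   `n_hidden`, `restarts` (per-restart seed/SSE/epochs tibble), `control`.
#' @examples
#' x <- matrix(runif(40, -1, 1), 20, 2)
#' y <- 0.3 * x[, 1] - 0.2 * x[, 2]
#' fit <- train_lm(x, y, n_hidden = 4, control = lm_control(n_restarts = 2))
#' fit$final_sse
#' @export
train_lm <- function(x, y, n_hidden, control = lm_control()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  check_that(nrow(x) == length(y) && length(y) >= 1,
             "`x` and `y` must have matching, nonzero length")
  check_that(all(is.finite(x)) && all(is.finite(y)),
             "non-finite values in training data")

  seeds <- control$seed + seq_len(control$n_restarts) - 1L
  runs <- lapply(seeds, function(s) {
    lm_run(x, y, init_params(ncol(x), n_hidden, seed = s), control)
  })
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best <- which.min(sses)
  structure(
    list(params = runs[[best]]$params,
         final_sse = sses[best],
         epochs_run = runs[[best]]$epochs,
         sse_trace = runs[[best]]$sse_trace,
         n_hidden = n_hidden,
         restarts = tibble(seed = seeds, sse = sses,
                           epochs = vapply(runs, `[[`, integer(1), "epochs")),
         control = control),
    class = "ffnn_fit"
  )
}

#' @export
print.ffnn_fit <- function(x, ...) {
  cat(sprintf("<ffnn_fit> %d-%d-1, SSE %.3e after %d epochs (best of %d restarts)\n",
              ncol(x$params$hidden_weights), x$n_hidden, x$final_sse,
              x$epochs_run, nrow(x$restarts)))
  invisible(x)
}
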