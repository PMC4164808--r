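# Independent oracles and shared fixtures for the suite. Everything here is
# deliberately naive (loops, finite differences) so it cannot share a bug
# with the vectorized implementation it checks.

fixture_test_ids <- c(4, 13, 16, 23, 29, 32, 36, 41, 46, 49)

# naive loop-based forward pass (oracle for ffnn_forward)
forward_loop_oracle <- function(params, x) {
  n_hidden <- nrow(params$hidden_weights)
  out <- numeric(nrow(x))
  for (r in seq_len(nrow(x))) {
    acc <- params$output_bias
    for (k in seq_len(n_hidden)) {
      z <- params$input_bias[k]
      for (j in seq_len(ncol(x))) {
        z <- z + params$hidden_weights[k, j] * x[r, j]
      }
      acc <- acc + params$output_weights[k] * tanh(z)
    }
    out[r] <- acc
  }
  out
}

# central finite-difference Jacobian (oracle for the analytic Jacobian)
fd_jacobian_oracle <- function(params, x, eps = 1e-6) {
  th <- fermga:::pack_params(params)
  n_in <- ncol(params$hidden_weights)
  n_hidden <- nrow(params$hidden_weights)
  sapply(seq_along(th), function(i) {
    up <- th; up[i] <- up[i] + eps
    dn <- th; dn[i] <- dn[i] - eps
    (ffnn_forward(fermga:::unpack_params(up, n_in, n_hidden), x) -
       ffnn_forward(fermga:::unpack_params(dn, n_in, n_hidden), x)) / (2 * eps)
  })
}

# scalar-loop error metrics (oracle for compute_metrics)
metrics_loop_oracle <- function(y_pred, y_exp) {
  n <- length(y_pred)
  mse <- 0; mae <- 0; mape <- 0
  for (i in seq_len(n)) {
    mse <- mse + (y_pred[i] - y_exp[i])^2 / n
    mae <- mae + abs(y_pred[i] - y_exp[i]) / n
    mape <- mape + abs(y_pred[i] - y_exp[i]) / y_exp[i] / n
  }
  mp <- mean(y_pred); me <- mean(y_exp)
  num <- sum((y_pred - mp) * (y_exp - me))
  r2 <- num^2 / (sum((y_pred - mp)^2) * sum((y_exp - me)^2))
  list(mse = mse, rmse = sqrt(mse), mae = mae, mape = mape, r_squared = r2)
}

# one shared trained model on the packaged dataset (trained lazily once;
# training takes well under a second)
fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- fit_activity_model(alpha_gal_design(), n_hidden = 10,
                                   control = lm_control(n_restarts = 10,
                                                        seed = 1))
    }
    cache
  }
})

# a small partitioned synthetic design used by several files
synthetic_design <- function(noise_sd = 0.1, seed = 1, ...) {
  spec <- quadratic_surface_spec(noise_sd = noise_sd, seed = seed, ...)
  d <- build_ccd(alpha_gal_factors())
  d <- split_design(d, fixture_test_ids)
  list(spec = spec, design = simulate_design_observations(d, spec))
}
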