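test_that("initialization is seeded, bounded, and counts parameters correctly", {
  p1 <- init_params(6, 10, seed = 3)
  p2 <- init_params(6, 10, seed = 3)
  p3 <- init_params(6, 10, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_equal(fermga:::n_free_params(p1), 81)
  th <- fermga:::pack_params(p1)
  expect_true(all(th >= -0.5 & th <= 0.5))
  expect_equal(fermga:::pack_params(fermga:::unpack_params(th, 6, 10)), th)
})

test_that("tansig is the tanh-shaped sigmoid with range (-1, 1)", {
  z <- seq(-20, 20, length.out = 401)
  expect_equal(tansig(z), tanh(z), tolerance = 1e-15)
  expect_equal(tansig(0), 0)
  expect_true(all(tansig(z) >= -1 & tansig(z) <= 1))
  zin <- seq(-5, 5, length.out = 101)   # strictly inside until saturation
  expect_true(all(tansig(zin) > -1 & tansig(zin) < 1))
  expect_equal(tansig(1000), 1)   # saturates without NaN
  expect_equal(tansig(-1000), -1)
})

test_that("forward pass matches hand evaluation and a loop oracle", {
  # zero weights: output is the output bias, whatever the input
  p0 <- init_params(6, 4, seed = 1)
  p0$hidden_weights[] <- 0
  p0$input_bias[] <- 0
  p0$output_weights[] <- 0
  p0$output_bias <- 0.7
  expect_equal(ffnn_forward(p0, runif(6)), 0.7)

  # 1-2-1 hand computation: tanh(1) + 0.5 tanh(-1) + 0.1
  p <- structure(list(hidden_weights = matrix(c(1, -1), 2, 1),
                      input_bias = c(0, 0),
                      output_weights = c(1, 0.5),
                      output_bias = 0.1), class = "ffnn_params")
  expect_equal(ffnn_forward(p, 1), tanh(1) + 0.5 * tanh(-1) + 0.1,
               tolerance = 1e-15)
  # odd symmetry: zero input and zero biases give zero output
  p$output_bias <- 0
  expect_equal(ffnn_forward(p, 0), 0)

  set.seed(8)
  for (i in 1:5) {
    pr <- init_params(5, 7, seed = i)
    x <- matrix(runif(20, -1, 1), 4, 5)
    expect_equal(ffnn_forward(pr, x), forward_loop_oracle(pr, x),
                 tolerance = 1e-12)
  }
  expect_error(ffnn_forward(pr, matrix(0, 2, 3)), "expects")
})

test_that("analytic Jacobian matches central finite differences", {
  set.seed(5)
  p <- init_params(4, 6, seed = 2)
  x <- matrix(runif(28, -1, 1), 7, 4)
  expect_equal(fermga:::ffnn_jacobian(p, x), fd_jacobian_oracle(p, x),
               tolerance = 1e-6)
})

test_that("LM interpolates a single point and tracks non-increasing SSE", {
  x <- matrix(c(0.2, -0.3, 0.5), 1, 3)
  fit <- train_lm(x, 0.4, n_hidden = 4,
                  control = lm_control(n_restarts = 1, seed = 2))
  expect_lt(fit$final_sse, 1e-10)
  expect_true(all(diff(fit$sse_trace) <= 0))
})

test_that("LM recovers a noiseless linear map as well as least squares", {
  set.seed(31)
  x <- matrix(runif(40, -1, 1), 20, 2)
  y <- 0.3 * x[, 1] - 0.2 * x[, 2]
  fit <- train_lm(x, y, n_hidden = 5,
                  control = lm_control(n_restarts = 3, seed = 1))
  rmse <- sqrt(fit$final_sse / length(y))
  # the linear model is the truth, so its residual (0) bounds what the
  # network should approach
  ls_rmse <- sqrt(mean(stats::lm(y ~ x)$residuals^2))
  expect_lt(rmse, 1e-3)
  expect_gte(rmse, ls_rmse)
})

test_that("LM recovers the function computed by a random 6-5-1 network", {
  teacher <- init_params(6, 5, seed = 77)
  set.seed(78)
  x <- matrix(runif(300, -1, 1), 50, 6)
  y <- ffnn_forward(teacher, x)
  fit <- train_lm(x, y, n_hidden = 5,
                  control = lm_control(n_restarts = 5, seed = 10))
  expect_lt(sqrt(fit$final_sse / length(y)), 1e-4)
})

test_that("LM matches an independent Levenberg-Marquardt implementation", {
  # same residual function handed to minpack.lm: both should drive a small
  # noiseless problem to (near) machine-zero SSE
  set.seed(41)
  x <- matrix(runif(30, -1, 1), 15, 2)
  teacher <- init_params(2, 3, seed = 9)
  y <- ffnn_forward(teacher, x)
  ours <- train_lm(x, y, n_hidden = 3,
                   control = lm_control(n_restarts = 3, seed = 5))
  start <- fermga:::pack_params(init_params(2, 3, seed = 5))
  ref <- minpack.lm::nls.lm(
    par = start,
    fn = function(th) ffnn_forward(fermga:::unpack_params(th, 2, 3), x) - y,
    control = minpack.lm::nls.lm.control(maxiter = 1000)
  )
  expect_lt(ours$final_sse, 1e-10)
  expect_lt(sum(ref$fvec^2), 1e-6)
  expect_lte(ours$final_sse, sum(ref$fvec^2))
})

test_that("hidden-size selection follows the stated rules", {
  sim <- synthetic_design(noise_sd = 0.1, seed = 6)
  ctrl <- lm_control(n_restarts = 2, seed = 3)
  one <- select_hidden_size(sim$design, sizes = 5, control = ctrl)
  expect_equal(one$n_hidden, 5)          # degenerate sweep
  sw <- select_hidden_size(sim$design, sizes = c(3, 6, 10), control = ctrl)
  expect_true(sw$n_hidden %in% c(3, 6, 10))
  # selected size is the row with minimal test RMSE
  expect_equal(min(sw$sweep$rmse),
               sw$sweep$rmse[sw$sweep$n_hidden == sw$n_hidden])
  expect_error(select_hidden_size(sim$design, sizes = integer(0)), "non-empty")
})
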