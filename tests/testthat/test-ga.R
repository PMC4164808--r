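test_that("chromosome decoding maps bit fields linearly onto factor ranges", {
  f <- alpha_gal_factors()
  lows <- decode_chromosome(rep(0, 36), f)
  expect_equal(unname(as.numeric(lows)), f$low)
  highs <- decode_chromosome(rep(1, 36), f)
  expect_equal(unname(as.numeric(highs)), f$high)
  # temperature field 010101 = 21 -> 32 + 8 * 21 / 63
  bits <- rep(0, 36)
  bits[1:6] <- c(0, 1, 0, 1, 0, 1)
  expect_equal(decode_chromosome(bits, f)[[1, "temperature_C"]],
               32 + 8 * 21 / 63)
  expect_error(decode_chromosome(rep(0, 35), f), "chromosome length")
  expect_error(decode_chromosome(rep(2, 36), f), "0 or 1")
})

test_that("fitness is exactly the forward pass on the decoded, scaled input", {
  m <- fixture_model()
  set.seed(14)
  bits <- matrix(sample(0:1, 36 * 20, replace = TRUE), 20, 36)
  fit <- evaluate_fitness(m, bits)
  nat <- decode_chromosome(bits, m$factors)
  xs <- as.matrix(scaler_transform(m$scaler_x, nat))
  expect_equal(fit, ffnn_forward(m$fit$params, xs), tolerance = 1e-12)
})

test_that("a zero-weight network gives constant fitness", {
  m <- fixture_model()
  m0 <- m
  m0$fit$params$hidden_weights[] <- 0
  m0$fit$params$output_weights[] <- 0
  m0$fit$params$output_bias <- 0.2
  set.seed(15)
  bits <- matrix(sample(0:1, 36 * 8, replace = TRUE), 8, 36)
  expect_equal(evaluate_fitness(m0, bits), rep(0.2, 8))
})

test_that("the GA respects factor bounds, monotone elitist trace, determinism", {
  m <- fixture_model()
  ctrl <- ga_control(max_generations = 60, seed = 9)
  r1 <- ga_evolve(m, ctrl)
  r2 <- ga_evolve(m, ctrl)
  expect_identical(r1$best_bits, r2$best_bits)
  expect_equal(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_ever_fitness) >= 0))
  # elitism >= 1 also makes the per-generation best non-decreasing
  expect_true(all(diff(r1$trace$best_fitness) >= -1e-12))
  f <- m$factors
  for (nm in f$name) {
    v <- r1$top_conditions[[nm]]
    expect_true(all(v >= f$low[f$name == nm] & v <= f$high[f$name == nm]))
  }
})

test_that("without variation operators the population never changes", {
  m <- fixture_model()
  ctrl <- ga_control(crossover_prob = 0, mutation_prob = 0,
                     elitism = 36, max_generations = 25, seed = 3)
  r <- ga_evolve(m, ctrl)
  expect_equal(diff(r$trace$best_fitness), rep(0, 24))
  expect_equal(diff(r$trace$mean_fitness), rep(0, 24))
})

test_that("the GA finds the exhaustive optimum of a 12-bit problem", {
  # two-factor surrogate: train a tiny network, then enumerate all 4096
  # chromosomes as the oracle
  factors <- dplyr::bind_rows(factor_spec("a", "", 0, 1),
                              factor_spec("b", "", 0, 1))
  d <- build_ccd(factors, core = "full", alpha = 1.4, n_center = 4)
  spec <- quadratic_surface_spec(factors = factors,
                                 optimum_coded = c(0.3, -0.4),
                                 peak_activity = 8,
                                 curvature = c(-1, -1.5),
                                 noise_sd = 0, seed = 2)
  sim <- simulate_design_observations(d, spec)
  m <- fit_activity_model(sim, n_hidden = 4,
                          control = lm_control(n_restarts = 3, seed = 21))
  all_bits <- as.matrix(expand.grid(rep(list(0:1), 12)))[, 12:1]
  exhaustive <- max(evaluate_fitness(m, all_bits))
  r <- ga_evolve(m, ga_control(chromosome_length = 12, seed = 5))
  expect_gte(r$best_fitness, 0.999 * exhaustive)
})
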