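test_that("the quadratic truth peaks exactly at its stated optimum", {
  spec <- quadratic_surface_spec()
  f <- make_quadratic_truth(spec)
  expect_equal(f(spec$optimum_coded), spec$peak_activity)
  # unit curvature: one coded unit off in one factor costs exactly 1
  s1 <- quadratic_surface_spec(curvature = rep(-1, 6), peak_activity = 10)
  f1 <- make_quadratic_truth(s1)
  x <- s1$optimum_coded
  x[3] <- x[3] + 1
  expect_equal(f1(x), 9)
  # lattice argmax sits at the optimum within lattice spacing
  grid <- as.matrix(expand.grid(rep(list(seq(-2, 2, by = 0.25)), 2)))
  s2 <- quadratic_surface_spec(
    factors = dplyr::bind_rows(factor_spec("a", "", 0, 1),
                               factor_spec("b", "", 0, 1)),
    optimum_coded = c(0.4, -0.6), peak_activity = 5,
    curvature = c(-1, -1), noise_sd = 0)
  f2 <- make_quadratic_truth(s2)
  best <- grid[which.max(f2(grid)), ]
  expect_true(all(abs(best - c(0.4, -0.6)) <= 0.25))
})

test_that("invalid curvature is rejected", {
  expect_error(quadratic_surface_spec(curvature = c(rep(-1, 5), 0)),
               "negative")
  expect_error(quadratic_surface_spec(curvature = rep(-1, 3)),
               "one entry per factor")
})

test_that("interaction terms contribute bilinearly", {
  inter <- matrix(0, 6, 6)
  inter[1, 2] <- 0.5
  spec <- quadratic_surface_spec(interactions = inter)
  f <- make_quadratic_truth(spec)
  x <- spec$optimum_coded + c(1, 1, 0, 0, 0, 0)
  plain <- make_quadratic_truth(quadratic_surface_spec())
  expect_equal(f(x), plain(x) + 0.5)
})

test_that("simulated observations are seeded, unbiased, and floored at zero", {
  d <- build_ccd(alpha_gal_factors())
  spec0 <- quadratic_surface_spec(noise_sd = 0, seed = 5)
  sim0 <- simulate_design_observations(d, spec0)
  expect_equal(sim0$activity_U_per_mL, sim0$truth_U_per_mL)  # no noise

  spec1 <- quadratic_surface_spec(noise_sd = 0.1, seed = 6)
  a <- simulate_design_observations(d, spec1)
  b <- simulate_design_observations(d, spec1)
  expect_identical(a$activity_U_per_mL, b$activity_U_per_mL)

  # CLT check: centre-replicate residuals over 200 seeds average to zero
  centre <- d$role == "center"
  res <- unlist(lapply(1:200, function(s) {
    sim <- simulate_design_observations(
      d, quadratic_surface_spec(noise_sd = 0.1, seed = s))
    sim$activity_U_per_mL[centre] - sim$truth_U_per_mL[centre]
  }))
  expect_equal(length(res), 1200)
  expect_lt(abs(mean(res)), 3 * 0.1 / sqrt(1200))

  # a surface far below zero must floor and warn
  spec_low <- quadratic_surface_spec(peak_activity = 0.01, noise_sd = 0.5,
                                     seed = 7)
  expect_warning(low <- simulate_design_observations(d, spec_low), "floored")
  expect_true(all(low$activity_U_per_mL >= 0))
})
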