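test_that("run counts follow core_size + 2k + n_center across configurations", {
  for (k in 2:8) {
    factors <- dplyr::bind_rows(lapply(seq_len(k), function(i) {
      factor_spec(paste0("f", i), "", 0, 1)
    }))
    d_full <- build_ccd(factors, core = "full", alpha = 1.5, n_center = 3)
    expect_equal(nrow(d_full), 2^k + 2 * k + 3)
    expect_equal(sum(d_full$role == "factorial"), 2^k)
    expect_equal(sum(d_full$role == "axial"), 2 * k)
    if (k >= 3) {
      d_half <- build_ccd(factors, core = "half_fraction", alpha = 2,
                          n_center = 5)
      expect_equal(nrow(d_half), 2^(k - 1) + 2 * k + 5)
    }
  }
})

test_that("the six-factor half-fraction design has the published structure", {
  d <- build_ccd(alpha_gal_factors(), core = "half_fraction", alpha = 2,
                 n_center = 6)
  expect_equal(nrow(d), 50)
  expect_equal(as.integer(table(d$role)[c("factorial", "axial", "center")]),
               c(32L, 12L, 6L))
  expect_equal(d$run_id, 1:50)
  # temperature levels from the level formula: axial 32/40, factorial 34/38,
  # centre 36
  expect_setequal(unique(d$temperature_C), c(32, 34, 36, 38, 40))
  expect_setequal(unique(d$temperature_C[d$role == "factorial"]), c(34, 38))
})

test_that("invalid designs are rejected", {
  two <- dplyr::bind_rows(factor_spec("a", "", 0, 1), factor_spec("b", "", 0, 1))
  expect_error(build_ccd(two, core = "half_fraction"),
               class = "fermga_invalid_design")
  bad <- tibble::tibble(name = "a", units = "", low = 0, high = Inf)
  expect_error(build_ccd(dplyr::bind_rows(bad, factor_spec("b", "", 0, 1))),
               "non-finite")
  expect_error(factor_spec("t", "", 5, 5), "low")
})

test_that("code_levels and decode_levels are exact inverses", {
  d <- build_ccd(alpha_gal_factors())
  # worked values: axial temperature 40 -> +2, factorial 38 -> +1
  cd <- code_levels(d, c(40, 7, 170, 1, 2.5, 1))
  expect_equal(cd[[1, "coded_temperature_C"]], 2)
  expect_equal(code_levels(d, c(38, 7, 170, 1, 2.5, 1))[[1, 1]], 1)
  # centres map to zero, and back
  centres <- (alpha_gal_factors()$low + alpha_gal_factors()$high) / 2
  expect_equal(unname(as.numeric(code_levels(d, centres))), rep(0, 6))
  expect_equal(unname(as.numeric(decode_levels(d, rep(0, 6)))), centres)
  # axial low on pH, factorial raffinose
  expect_equal(decode_levels(d, c(0, -2, 0, 0, 0, 0))[[1, "pH"]], 6)
  expect_equal(decode_levels(d, c(0, 0, 0, 0, 1, 0))[[1, "raffinose_g_per_100mL"]], 3.0)

  set.seed(99)
  for (i in 1:25) {
    z <- runif(6, -2, 2)
    back <- as.numeric(code_levels(d, as.numeric(decode_levels(d, z))))
    expect_equal(back, z, tolerance = 1e-12)
  }
  expect_error(code_levels(d, c(1, 2, 3)), "factor columns")
})

test_that("the packaged fixture is reproduced exactly by the CCD builder", {
  d <- alpha_gal_design()
  built <- build_ccd(alpha_gal_factors(), core = "half_fraction", alpha = 2,
                     n_center = 6)
  f <- alpha_gal_factors()$name
  expect_equal(as.matrix(as.data.frame(built[f])),
               as.matrix(as.data.frame(d[f])), ignore_attr = TRUE)
  expect_equal(built$role, d$role)
  # natural values are also recovered from each run's role-implied coded
  # vector alone
  redecoded <- decode_levels(d, d[paste0("coded_", f)])
  expect_equal(as.matrix(as.data.frame(redecoded)),
               as.matrix(as.data.frame(d[f])), ignore_attr = TRUE)
})

test_that("split_design assigns partitions and validates ids", {
  d <- build_ccd(alpha_gal_factors())
  s <- split_design(d, fixture_test_ids)
  expect_equal(sum(s$partition == "train"), 40)
  expect_equal(sum(s$partition == "test"), 10)
  expect_equal(sum(split_design(d, integer(0))$partition == "train"), 50)
  expect_equal(sum(split_design(d, d$run_id)$partition == "test"), 50)
  expect_error(split_design(d, c(1, 99)), "unknown run ids")
  expect_error(split_design(d, c(3, 3)), "duplicates")
})
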