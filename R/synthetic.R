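#' Specify a synthetic quadratic response surface
#'
#' Describes the ground truth the analysis pipeline assumes it is
#' recovering: a smooth response with a single interior maximum over the
#' coded factor space, optional bilinear interactions, and homoscedastic
#' Gaussian observation noise. The defaults emulate the packaged
#' fermentation system: six factors, a peak of 10 U/mL at an off-centre
#' interior optimum, curvature calibrated so the noiseless response over
#' the 50 design points spans about 5 U/mL (the packaged dataset's
#' observed activities span 2.8-7.5 U/mL), and 0.1 U/mL measurement noise
#' (about the replicate spread of the centre points).
#'
#' @param factors Factor tibble (default [alpha_gal_factors()]).
#' @param optimum_coded True argmax in coded units (inside `(-alpha,
#'   alpha)` per factor).
#' @param peak_activity Response at the optimum, U/mL.
#' @param curvature Negative quadratic coefficient per coded factor
#'   (U/mL per coded-unit squared).
#' @param interactions Optional symmetric `k x k` matrix of bilinear
#'   coefficients (only the upper triangle is used).
#' @param noise_sd Observation noise standard deviation, U/mL.
#' @param seed Seed for [simulate_design_observations()].
#' @return A list of class `synthetic_surface_spec`.
#' @export
quadratic_surface_spec <- function(factors = alpha_gal_factors(),
                                   optimum_coded = c(0.5, 0.25, 0.75,
                                                     0.5, -0.5, 0.5),
                                   peak_activity = 10,
                                   curvature = rep(-0.45, nrow(factors)),
                                   interactions = NULL,
                                   noise_sd = 0.1,
                                   seed = 1) {
  k <- nrow(factors)
  check_that(length(optimum_coded) == k && length(curvature) == k,
             "`optimum_coded` and `curvature` need one entry per factor")
  check_that(all(is.finite(curvature)) && all(curvature < 0),
             "all curvature entries must be negative (single interior maximum)")
  check_that(is.finite(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  if (!is.null(interactions)) {
    check_that(is.matrix(interactions) && all(dim(interactions) == k),
               "`interactions` must be a k x k matrix")
  }
  structure(list(factors = factors, optimum_coded = optimum_coded,
                 peak_activity = peak_activity, curvature = curvature,
                 interactions = interactions, noise_sd = noise_sd,
                 seed = seed),
            class = "synthetic_surface_spec")
}

#' Ground-truth response function of a synthetic surface
#'
#' Returns `f(x) = peak + sum(curvature * (x - opt)^2) + sum over i < j of
#' interactions[i, j] * (x_i - opt_i) * (x_j - opt_j)` as a function of
#' coded settings; `f(optimum_coded) == peak_activity` exactly.
#'
#' @param spec A [quadratic_surface_spec()].
#' @return A function taking a coded vector or matrix (rows = points) and
#'   returning activities in U/mL.
#' @examples
#' f <- make_quadratic_truth(quadratic_surface_spec())
#' f(quadratic_surface_spec()$optimum_coded)  # == 10
#' @export
make_quadratic_truth <- function(spec) {
  check_that(inherits(spec, "synthetic_surface_spec"),
             "`spec` must come from quadratic_surface_spec()")
  k <- length(spec$curvature)
  force(spec)
  function(coded) {
    if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1L)
    check_that(ncol(coded) == k, "wrong number of coded columns")
    d <- sweep(as.matrix(coded), 2, spec$optimum_coded)
    y <- spec$peak_activity + drop(d^2 %*% spec$curvature)
    if (!is.null(spec$interactions)) {
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          b <- spec$interactions[i, j]
          if (b != 0) y <- y + b * d[, i] * d[, j]
        }
      }
    }
    y
  }
}

#' Simulate observed activities on a design
#'
#' Fills a design table's `activity_U_per_mL` column with the synthetic
#' truth evaluated at each run's coded settings plus seeded
#' `Normal(0, noise_sd)` observation noise. Negative draws are floored at
#' zero (activities cannot be negative) with a warning.
#'
#' @param design A `ccd_design` (its factor set must match `spec`).
#' @param spec A [quadratic_surface_spec()].
#' @return The design with `activity_U_per_mL` filled and a `truth_U_per_mL`
#'   column carrying the noiseless response.
#' @examples
#' d <- build_ccd(alpha_gal_factors())
#' sim <- simulate_design_observations(d, quadratic_surface_spec(seed = 11))
#' head(sim$activity_U_per_mL)
#' @export
simulate_design_observations <- function(design, spec) {
  f <- make_quadratic_truth(spec)
  coded <- as.matrix(code_levels(design, design[, ccd_factors(design)$name]))
  truth <- f(coded)
  set.seed(spec$seed)
  obs <- truth + rnorm(length(truth), 0, spec$noise_sd)
  if (any(obs < 0)) {
    warn(sprintf("%d simulated activities were negative and floored at 0",
                 sum(obs < 0)))
    obs[obs < 0] <- 0
  }
  design$truth_U_per_mL <- truth
  design$activity_U_per_mL <- obs
  design
}
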