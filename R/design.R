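#' Define a fermentation factor
#'
#' A factor is described by its name, units, and the *axial* (star-point) low
#' and high levels in natural units. For a central composite design (CCD)
#' with axial distance `alpha`, the centre point is `(low + high) / 2` and the
#' factorial levels sit at `centre +/- (high - low) / (2 * alpha)`, so the
#' axial points land exactly on `low` and `high`.
#'
#' @param name Column name used for this factor in design tables.
#' @param units Human-readable units (e.g. `"degC"`, `"rpm"`, `"g/100 mL"`).
#' @param low,high Axial low/high levels in natural units (`low < high`).
#'
#' @return A one-row tibble with columns `name`, `units`, `low`, `high`.
#'   Bind rows of these to describe a multi-factor design.
#' @examples
#' factor_spec("temperature_C", "degC", 32, 40)
#' @export
factor_spec <- function(name, units, low, high) {
  check_that(is.character(name) && length(name) == 1L && nzchar(name),
             "`name` must be a non-empty string")
  check_that(is.numeric(low) && is.numeric(high) &&
               is.finite(low) && is.finite(high),
             "factor bounds must be finite numbers")
  check_that(low < high, sprintf("factor '%s': `low` must be < `high`", name))
  tibble(name = name, units = units, low = as.numeric(low),
         high = as.numeric(high))
}

#' The six alpha-galactosidase fermentation factors
#'
#' Axial ranges for the six factors screened for intracellular
#' alpha-galactosidase production by *Acinetobacter* sp. in submerged
#' fermentation: temperature, pH, agitation speed, tryptone (nitrogen
#' source), raffinose (carbon source and inducer) and dipotassium phosphate.
#'
#' @return A six-row factor tibble (see [factor_spec()]).
#' @examples
#' alpha_gal_factors()
#' @export
alpha_gal_factors <- function() {
  dplyr::bind_rows(
    factor_spec("temperature_C",         "degC",     32,  40),
    factor_spec("pH",                    "",          6,   8),
    factor_spec("agitation_rpm",         "rpm",     150, 190),
    factor_spec("tryptone_g_per_100mL",  "g/100 mL",  0,   2),
    factor_spec("raffinose_g_per_100mL", "g/100 mL", 1.5, 3.5),
    factor_spec("k2hpo4_g_per_100mL",    "g/100 mL", 0.5, 1.5)
  )
}

new_ccd_design <- function(runs, factors, alpha) {
  structure(runs, factors = factors, alpha = alpha,
            class = c("ccd_design", class(tibble())))
}

#' @export
print.ccd_design <- function(x, ...) {
  cat(sprintf("<ccd_design> %d runs, %d factors, alpha = %g\n",
              nrow(x), nrow(attr(x, "factors")), attr(x, "alpha")))
  NextMethod()
}

#' Accessors for a CCD design table
#'
#' @param design A design built by [build_ccd()] or loaded by
#'   [alpha_gal_design()].
#' @return `ccd_factors()` the factor tibble; `ccd_alpha()` the axial
#'   distance in coded units.
#' @export
ccd_factors <- function(design) {
  f <- attr(design, "factors")
  check_that(is.data.frame(f),
             "not a ccd_design: factor metadata missing (rebuild with build_ccd())")
  f
}

#' @rdname ccd_factors
#' @export
ccd_alpha <- function(design) {
  a <- attr(design, "alpha")
  check_that(is.numeric(a) && length(a) == 1L && a > 0,
             "not a ccd_design: alpha attribute missing")
  a
}

# Half-fraction factorial core in Yates order: the first factor varies
# slowest, the last *basic* factor fastest, and the dropped factor is the
# product of the basic columns (for k = 6 this is the resolution-VI fraction
# I = +ABCDEF, which reproduces the packaged fixture's printed signs).
factorial_core <- function(k, core) {
  if (core == "full") {
    basic <- k
  } else {
    check_that(k >= 3,
               "half-fraction core needs at least 3 factors",
               class = "fermga_invalid_design")
    basic <- k - 1L
  }
  g <- expand.grid(rep(list(c(-1, 1)), basic))[, rev(seq_len(basic)), drop = FALSE]
  m <- as.matrix(g)
  if (core == "half_fraction") m <- cbind(m, apply(m, 1, prod))
  dimnames(m) <- NULL
  m
}

#' Build a central composite design
#'
#' Constructs the coded and natural-unit run table of a CCD: a full or
#' half-fraction two-level factorial core, `2 * k` axial (star) runs at
#' coded distance `+/- alpha`, and `n_center` replicated centre runs.
#' Natural units are derived from each factor's axial bounds, so the axial
#' runs land exactly on `low` and `high`.
#'
#' Runs are ordered factorial core (Yates order), then axial points in
#' factor order (low before high), then centre replicates; `run_id` is
#' contiguous from 1. All runs start in the `"train"` partition; use
#' [split_design()] to hold out test runs.
#'
#' @param factors A factor tibble (rows from [factor_spec()]).
#' @param core `"half_fraction"` (2^(k-1) runs, k >= 3) or `"full"` (2^k).
#' @param alpha Axial distance in coded units (> 0); factorial points sit
#'   at coded +/- 1.
#' @param n_center Number of centre replicates (>= 0).
#'
#' @return A `ccd_design` tibble with columns `run_id`, `role`
#'   (factorial/axial/center), `partition`, one `coded_<name>` and one
#'   natural column per factor, and an empty `activity_U_per_mL` column.
#' @examples
#' build_ccd(alpha_gal_factors(), core = "half_fraction", alpha = 2, n_center = 6)
#' @export
build_ccd <- function(factors, core = c("half_fraction", "full"),
                      alpha = 2, n_center = 6) {
  core <- match.arg(core)
  check_that(is.data.frame(factors) &&
               all(c("name", "low", "high") %in% names(factors)),
             "`factors` must be a factor tibble (see factor_spec())")
  k <- nrow(factors)
  check_that(k >= 2 && k <= 12, "between 2 and 12 factors supported")
  check_that(all(is.finite(factors$low)) && all(is.finite(factors$high)),
             "non-finite factor bounds")
  check_that(all(factors$low < factors$high), "each factor needs low < high")
  check_that(is.numeric(alpha) && length(alpha) == 1L && alpha > 0,
             "`alpha` must be a positive scalar")
  check_that(n_center >= 0, "`n_center` must be >= 0")

  fac <- factorial_core(k, core)
  axial <- matrix(0, 2L * k, k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -alpha
    axial[2L * i, i] <- alpha
  }
  centre <- matrix(0, n_center, k)
  coded <- rbind(fac, axial, centre)
  role <- rep(c("factorial", "axial", "center"),
              c(nrow(fac), nrow(axial), n_center))

  mid <- (factors$low + factors$high) / 2
  halfstep <- (factors$high - factors$low) / (2 * alpha)
  natural <- sweep(sweep(coded, 2, halfstep, "*"), 2, mid, "+")

  coded_df <- as_tibble(as.data.frame(coded),
                        .name_repair = ~ paste0("coded_", factors$name))
  natural_df <- as_tibble(as.data.frame(natural),
                          .name_repair = ~ factors$name)
  runs <- dplyr::bind_cols(
    tibble(run_id = seq_len(nrow(coded)), role = role, partition = "train"),
    coded_df, natural_df,
    tibble(activity_U_per_mL = NA_real_)
  )
  new_ccd_design(runs, factors, alpha)
}

natural_matrix <- function(design, data = design) {
  f <- ccd_factors(design)
  check_that(all(f$name %in% colnames(data)),
             "data is missing natural-unit factor columns")
  as.matrix(as.data.frame(data)[, f$name, drop = FALSE])
}

#' Convert between natural and coded factor levels
#'
#' `code_levels()` maps natural-unit settings to coded units
#' (`(x - centre) * 2 * alpha / (high - low)`, so factorial levels are
#' +/- 1 and axial levels +/- alpha); `decode_levels()` is its exact
#' inverse. The two round-trip to machine precision.
#'
#' @param design A `ccd_design` (provides factor bounds and alpha).
#' @param natural,coded A data frame / matrix with one column per factor
#'   (factor-name columns for `natural`, any names positionally for
#'   `coded`), or a single numeric vector of length `k`.
#' @return A tibble with one column per factor.
#' @examples
#' d <- build_ccd(alpha_gal_factors())
#' code_levels(d, c(38, 7, 170, 1, 2.5, 1))
#' decode_levels(d, c(1, 0, 0, 0, 0, 0))
#' @export
code_levels <- function(design, natural) {
  f <- ccd_factors(design)
  a <- ccd_alpha(design)
  x <- coerce_levels(natural, f)
  mid <- (f$low + f$high) / 2
  coded <- sweep(sweep(x, 2, mid), 2, (f$high - f$low) / (2 * a), "/")
  as_tibble(as.data.frame(coded), .name_repair = ~ paste0("coded_", f$name))
}

#' @rdname code_levels
#' @export
decode_levels <- function(design, coded) {
  f <- ccd_factors(design)
  a <- ccd_alpha(design)
  x <- coerce_levels(coded, f)
  mid <- (f$low + f$high) / 2
  natural <- sweep(sweep(x, 2, (f$high - f$low) / (2 * a), "*"), 2, mid, "+")
  as_tibble(as.data.frame(natural), .name_repair = ~ f$name)
}

coerce_levels <- function(x, factors) {
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(as.data.frame(x))
  check_that(ncol(x) == nrow(factors),
             sprintf("expected %d factor columns, got %d", nrow(factors), ncol(x)))
  storage.mode(x) <- "double"
  x
}

#' Assign train/test partitions to design runs
#'
#' Marks the runs named in `test_ids` as the `"test"` partition and all
#' other runs as `"train"`, the hold-out scheme used to judge the neural
#' network surrogate on runs it never saw.
#'
#' @param design A `ccd_design`.
#' @param test_ids Integer run ids to hold out (subset of `design$run_id`,
#'   no duplicates; may be empty).
#' @return The design with its `partition` column reassigned.
#' @examples
#' d <- build_ccd(alpha_gal_factors())
#' table(split_design(d, c(4, 13, 16))$partition)
#' @export
split_design <- function(design, test_ids) {
  check_that(!anyDuplicated(test_ids), "`test_ids` contains duplicates")
  unknown <- setdiff(test_ids, design$run_id)
  check_that(length(unknown) == 0,
             paste0("unknown run ids: ", paste(unknown, collapse = ", ")))
  design$partition <- ifelse(design$run_id %in% test_ids, "test", "train")
  design
}
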