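#' The 50-run alpha-galactosidase production design
#'
#' The packaged central composite design (half-fraction factorial core,
#' axial distance 2, six centre replicates) for intracellular
#' alpha-galactosidase production by *Acinetobacter* sp.: 32 factorial,
#' 12 axial and 6 centre runs over temperature, pH, agitation, tryptone,
#' raffinose and K2HPO4, each with the measured enzyme activity (U/mL).
#' Forty runs carry the `"train"` partition and ten the `"test"` partition,
#' the split used to validate the neural-network surrogate.
#'
#' The `predicted_U_per_mL` column carries the surrogate predictions
#' reported alongside the original measurements; it is auxiliary data (used
#' e.g. to exercise the error-metric suite) and plays no role in model
#' fitting, which always retrains from the observed activities.
#'
#' @return A `ccd_design` tibble of 50 runs with coded and natural factor
#'   columns, `role`, `partition`, `activity_U_per_mL` and
#'   `predicted_U_per_mL`.
#' @examples
#' d <- alpha_gal_design()
#' dplyr::count(d, partition)
#' @export
alpha_gal_design <- function() {
  path <- system.file("extdata", "alpha_gal_ccd.csv", package = "fermga",
                      mustWork = TRUE)
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  factors <- alpha_gal_factors()
  alpha <- 2
  nat <- as.matrix(raw[, factors$name])
  mid <- (factors$low + factors$high) / 2
  coded <- sweep(sweep(nat, 2, mid), 2, (factors$high - factors$low) / (2 * alpha), "/")
  n_off <- rowSums(coded != 0)
  role <- ifelse(n_off == 0, "center",
                 ifelse(n_off == 1 & apply(abs(coded), 1, max) == alpha,
                        "axial", "factorial"))
  coded_df <- as_tibble(as.data.frame(coded),
                        .name_repair = ~ paste0("coded_", factors$name))
  runs <- dplyr::bind_cols(
    tibble(run_id = raw$run_id, role = role, partition = raw$partition),
    coded_df,
    raw[, c(factors$name, "activity_U_per_mL", "predicted_U_per_mL")]
  )
  new_ccd_design(runs, factors, alpha)
}
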