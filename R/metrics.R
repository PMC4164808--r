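#' Error metrics for predicted vs experimental activities
#'
#' Computes the model-assessment suite used to judge the neural-network
#' surrogate: mean squared error `MSE = mean((y_p - y_e)^2)`, its square
#' root RMSE, mean absolute error MAE, mean absolute percentage error
#' `MAPE = mean(|y_p - y_e| / y_e)` (kept as a fraction, not x100), and two
#' flavours of the coefficient of determination: `r_squared`, the squared
#' Pearson correlation between predictions and observations (the headline
#' figure, matching the observed-vs-predicted correlation-chart reading),
#' and `r_squared_ss = 1 - SS_res / SS_tot` as a secondary column.
#'
#' MAPE is undefined when any experimental value is zero; it is then
#' reported as `NA` with a warning while the other metrics are still
#' computed.
#'
#' @param y_pred Numeric vector of predicted values.
#' @param y_exp Numeric vector of experimental (observed) values, same
#'   length.
#' @return A one-row tibble: `n`, `mse`, `rmse`, `mae`, `mape`,
#'   `r_squared`, `r_squared_ss`.
#' @examples
#' compute_metrics(c(2.5, 4.78), c(2.80, 4.70))
#' @export
compute_metrics <- function(y_pred, y_exp) {
  check_that(is.numeric(y_pred) && is.numeric(y_exp), "inputs must be numeric")
  check_that(length(y_pred) == length(y_exp),
             sprintf("length mismatch: %d predictions vs %d observations",
                     length(y_pred), length(y_exp)))
  n <- length(y_pred)
  check_that(n >= 1, "need at least one pair")
  check_that(all(is.finite(y_pred)) && all(is.finite(y_exp)),
             "non-finite values in inputs")

  err <- y_pred - y_exp
  mse <- mean(err^2)
  mae <- mean(abs(err))
  if (any(y_exp == 0)) {
    warn("y_exp contains zeros; MAPE is undefined and reported as NA")
    mape <- NA_real_
  } else {
    mape <- mean(abs(err) / abs(y_exp))
  }
  if (n >= 2 && stats::sd(y_pred) > 0 && stats::sd(y_exp) > 0) {
    r2 <- cor(y_pred, y_exp)^2
  } else {
    r2 <- NA_real_
  }
  sst <- sum((y_exp - mean(y_exp))^2)
  r2ss <- if (sst > 0) 1 - sum(err^2) / sst else NA_real_
  tibble(n = n, mse = mse, rmse = sqrt(mse), mae = mae, mape = mape,
         r_squared = r2, r_squared_ss = r2ss)
}
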