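#' Fit a min-max scaler to [-1, +1]
#'
#' Records the per-column minimum and maximum of `data` so that
#' [scaler_transform()] maps each column affinely onto `[-1, +1]`
#' (`min -> -1`, `max -> +1`), the normalization the network is trained
#' under. Fit the scaler on the training partition only and reuse it for
#' test rows and optimization candidates, so no information leaks from the
#' hold-out runs into the scaling.
#'
#' @param data A data frame or matrix of numeric columns.
#' @param cols Optional character vector of columns to scale (default: all
#'   numeric columns of `data`).
#' @return A `minmax_scaler`: a tibble with columns `variable`, `min`, `max`.
#' @examples
#' sc <- fit_scaler(data.frame(x = c(32, 36, 40)))
#' scaler_transform(sc, data.frame(x = c(32, 38, 40)))
#' @export
fit_scaler <- function(data, cols = NULL) {
  data <- as.data.frame(data)
  if (is.null(cols)) cols <- names(data)[vapply(data, is.numeric, logical(1))]
  check_that(length(cols) > 0, "no numeric columns to scale")
  check_that(all(cols %in% names(data)),
             paste0("missing columns: ",
                    paste(setdiff(cols, names(data)), collapse = ", ")))
  lo <- vapply(data[cols], min, numeric(1))
  hi <- vapply(data[cols], max, numeric(1))
  check_that(all(is.finite(lo)) && all(is.finite(hi)), "non-finite data")
  degenerate <- cols[hi <= lo]
  check_that(length(degenerate) == 0,
             paste0("constant column(s), cannot scale: ",
                    paste(degenerate, collapse = ", ")),
             class = "fermga_degenerate_scale")
  structure(tibble(variable = cols, min = unname(lo), max = unname(hi)),
            class = c("minmax_scaler", class(tibble())))
}

#' Apply or invert a fitted min-max scaler
#'
#' `scaler_transform()` maps natural-unit values `x` to
#' `2 * (x - min) / (max - min) - 1`; `scaler_inverse()` applies the exact
#' inverse. Values outside the fitted range extrapolate linearly beyond
#' `[-1, +1]` (optionally flagged with a warning), which happens e.g. when
#' the optimizer proposes a setting outside the span of the training runs.
#'
#' @param scaler A `minmax_scaler` from [fit_scaler()].
#' @param data A data frame/matrix containing the fitted variables, or a
#'   numeric vector (single fitted variable, or one value per variable in
#'   fitted order).
#' @param warn_extrapolate Warn when any value falls outside the fitted
#'   range (default `FALSE`; optimization routinely probes beyond the
#'   training span).
#' @return A tibble of the scaled (or back-transformed) variables, or a
#'   numeric vector when `data` was a vector.
#' @examples
#' sc <- fit_scaler(data.frame(activity = c(3.3, 7.5)))
#' scaler_inverse(sc, 0.5)  # 6.45
#' @export
scaler_transform <- function(scaler, data, warn_extrapolate = FALSE) {
  scaler_apply(scaler, data, inverse = FALSE, warn_extrapolate = warn_extrapolate)
}

#' @rdname scaler_transform
#' @export
scaler_inverse <- function(scaler, data) {
  scaler_apply(scaler, data, inverse = TRUE, warn_extrapolate = FALSE)
}

scaler_apply <- function(scaler, data, inverse, warn_extrapolate) {
  check_that(inherits(scaler, "minmax_scaler"), "`scaler` is not a minmax_scaler")
  vec_in <- is.numeric(data) && is.null(dim(data))
  if (vec_in) {
    m <- if (nrow(scaler) == 1L) matrix(data, ncol = 1L,
                                        dimnames = list(NULL, scaler$variable))
         else matrix(data, nrow = 1L, dimnames = list(NULL, scaler$variable))
  } else {
    m <- as.matrix(as.data.frame(data)[, scaler$variable, drop = FALSE])
  }
  lo <- scaler$min
  hi <- scaler$max
  if (inverse) {
    out <- sweep(sweep(sweep(m, 2, 2, "/") + 0.5, 2, hi - lo, "*"), 2, lo, "+")
  } else {
    out <- sweep(sweep(sweep(m, 2, lo), 2, hi - lo, "/"), 2, 2, "*") - 1
    if (warn_extrapolate && any(out < -1 | out > 1)) {
      warn("values outside the fitted range were extrapolated beyond [-1, 1]")
    }
  }
  if (vec_in) return(as.numeric(out))
  as_tibble(as.data.frame(out))
}

#' Serialize a scaler to / from a plain list
#'
#' Used when writing a trained model to JSON so the scaling travels with
#' the network weights.
#'
#' @param scaler A `minmax_scaler`.
#' @param x A list previously produced by `scaler_to_list()`.
#' @return A plain list, or the restored `minmax_scaler`.
#' @keywords internal
#' @export
scaler_to_list <- function(scaler) {
  list(variable = scaler$variable, min = scaler$min, max = scaler$max)
}

#' @rdname scaler_to_list
#' @export
scaler_from_list <- function(x) {
  structure(tibble(variable = as.character(x$variable),
                   min = as.numeric(x$min), max = as.numeric(x$max)),
            class = c("minmax_scaler", class(tibble())))
}
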