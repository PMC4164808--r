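#' Fit the neural-network surrogate to a design table
#'
#' The data-frame-first entry point for modelling: takes a `ccd_design`
#' with observed activities, fits min-max scalers for the factors and the
#' response on the *training* partition only, trains the
#' `n_in`-`n_hidden`-1 perceptron with Levenberg-Marquardt (best of
#' `control$n_restarts` seeded starts), and reports the error-metric suite
#' per partition on both the natural (U/mL) and scaled `[-1, 1]` response
#' scales.
#'
#' @param design A `ccd_design` whose `activity_U_per_mL` column is filled
#'   for every run; rows with `partition == "test"` are held out.
#' @param n_hidden Hidden-layer size (default 10, the selected topology
#'   for the packaged dataset).
#' @param control An [lm_control()] list.
#' @return An `activity_model`: `fit` (the [train_lm()] result),
#'   `scaler_x`, `scaler_y`, `factors`, `alpha`, `n_hidden`, and `metrics`
#'   (tibble with one row per partition x scale).
#' @examples
#' \donttest{
#' m <- fit_activity_model(alpha_gal_design(),
#'                         control = lm_control(n_restarts = 2, seed = 7))
#' glance(m)
#' }
#' @export
fit_activity_model <- function(design, n_hidden = 10, control = lm_control()) {
  factors <- ccd_factors(design)
  check_that("activity_U_per_mL" %in% names(design) &&
               !anyNA(design$activity_U_per_mL),
             "`design` must carry an observed activity for every run")
  train <- design[design$partition == "train", , drop = FALSE]
  check_that(nrow(train) >= 1, "no training rows in `design`")

  scaler_x <- fit_scaler(train, cols = factors$name)
  scaler_y <- fit_scaler(train, cols = "activity_U_per_mL")

  xs <- as.matrix(scaler_transform(scaler_x, train))
  ys <- scaler_transform(scaler_y, train$activity_U_per_mL)
  fit <- train_lm(xs, ys, n_hidden = n_hidden, control = control)

  model <- structure(
    list(fit = fit, scaler_x = scaler_x, scaler_y = scaler_y,
         factors = factors, alpha = ccd_alpha(design), n_hidden = n_hidden),
    class = "activity_model"
  )
  model$metrics <- model_metrics(model, design)
  model
}

model_metrics <- function(model, design) {
  parts <- unique(design$partition)
  purrr::map_dfr(parts, function(p) {
    rows <- design[design$partition == p, , drop = FALSE]
    if (nrow(rows) == 0) return(NULL)
    obs <- rows$activity_U_per_mL
    pred <- predict(model, rows)
    obs_s <- scaler_transform(model$scaler_y, obs)
    pred_s <- scaler_transform(model$scaler_y, pred)
    dplyr::bind_rows(
      dplyr::mutate(compute_metrics(pred, obs), partition = p, scale = "natural"),
      dplyr::mutate(compute_metrics(pred_s, obs_s), partition = p, scale = "scaled")
    )
  }) |>
    dplyr::relocate("partition", "scale")
}

#' Predict activity for new factor settings
#'
#' @param object An `activity_model`.
#' @param newdata A data frame with the natural-unit factor columns (any
#'   extra columns are ignored).
#' @param scale `"natural"` for U/mL (default) or `"scaled"` for the
#'   network's `[-1, 1]` output.
#' @param ... Unused.
#' @return Numeric vector of predicted activities.
#' @export
predict.activity_model <- function(object, newdata, scale = c("natural", "scaled"),
                                   ...) {
  scale <- match.arg(scale)
  xs <- as.matrix(scaler_transform(object$scaler_x, newdata))
  out <- ffnn_forward(object$fit$params, xs)
  if (scale == "natural") out <- scaler_inverse(object$scaler_y, out)
  out
}

#' @export
print.activity_model <- function(x, ...) {
  cat(sprintf("<activity_model> %d-%d-1 perceptron over %d factors\n",
              nrow(x$factors), x$n_hidden, nrow(x$factors)))
  print(x$metrics)
  invisible(x)
}

#' Tidy and summarize a fitted activity model
#'
#' `tidy()` returns one row per network parameter (layer, indices, value);
#' `glance()` one row with the topology, final SSE and headline train/test
#' R-squared values.
#'
#' @param x An `activity_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy activity_model
#' @export
tidy.activity_model <- function(x, ...) {
  p <- x$fit$params
  nh <- nrow(p$hidden_weights)
  nin <- ncol(p$hidden_weights)
  dplyr::bind_rows(
    tibble(layer = "hidden", from = rep(x$factors$name, each = nh),
           to = rep(seq_len(nh), nin), term = "weight",
           value = as.vector(p$hidden_weights)),
    tibble(layer = "hidden", from = NA_character_, to = seq_len(nh),
           term = "bias", value = p$input_bias),
    tibble(layer = "output", from = as.character(seq_len(nh)), to = 1L,
           term = "weight", value = p$output_weights),
    tibble(layer = "output", from = NA_character_, to = 1L, term = "bias",
           value = p$output_bias)
  )
}

#' @rdname tidy.activity_model
#' @method glance activity_model
#' @export
glance.activity_model <- function(x, ...) {
  pick <- function(part) {
    m <- x$metrics[x$metrics$partition == part & x$metrics$scale == "natural", ]
    if (nrow(m) == 0) tibble(r_squared = NA_real_, rmse = NA_real_) else
      tibble(r_squared = m$r_squared, rmse = m$rmse)
  }
  tr <- pick("train")
  te <- pick("test")
  tibble(n_in = nrow(x$factors), n_hidden = x$n_hidden, n_out = 1L,
         n_params = n_free_params(x$fit$params),
         final_sse = x$fit$final_sse, epochs_run = x$fit$epochs_run,
         train_r_squared = tr$r_squared, train_rmse = tr$rmse,
         test_r_squared = te$r_squared, test_rmse = te$rmse)
}

#' Select the hidden-layer size by trial and error
#'
#' Trains one network per candidate size with identical control (same
#' restart seeds), scores each on the held-out test partition, and selects
#' the size with the lowest test RMSE; ties are broken by lowest test MAPE,
#' then by fewest neurons. Metrics are computed on the natural (U/mL)
#' scale.
#'
#' @param design A partitioned `ccd_design` with observed activities.
#' @param sizes Integer vector of candidate hidden sizes (default `3:18`).
#' @param control An [lm_control()] list applied identically to every size.
#' @return A list: `n_hidden` (selected size), `sweep` (per-size tibble of
#'   test metrics), `models` (the fitted `activity_model`s, named by size).
#' @export
select_hidden_size <- function(design, sizes = 3:18, control = lm_control()) {
  check_that(length(sizes) >= 1, "`sizes` must be non-empty")
  check_that(all(sizes >= 1), "hidden sizes must be positive")
  check_that(any(design$partition == "test"),
             "`design` needs a test partition for size selection")
  models <- purrr::map(sizes, function(h) {
    fit_activity_model(design, n_hidden = h, control = control)
  })
  names(models) <- as.character(sizes)
  sweep_tbl <- purrr::map2_dfr(models, sizes, function(m, h) {
    te <- m$metrics[m$metrics$partition == "test" & m$metrics$scale == "natural", ]
    dplyr::mutate(te, n_hidden = h, partition = NULL, scale = NULL)
  }) |>
    dplyr::relocate("n_hidden")
  ranked <- dplyr::arrange(sweep_tbl, .data$rmse, .data$mape, .data$n_hidden)
  list(n_hidden = ranked$n_hidden[1], sweep = sweep_tbl, models = models)
}

#' Write / read a trained model as JSON
#'
#' Serializes the network weights, both scalers, the factor table and the
#' training control so a fitted surrogate can be reloaded and optimized
#' later without retraining.
#'
#' @param model An `activity_model`.
#' @param path File path for the JSON model.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` the restored `activity_model`.
#' @export
write_model_json <- function(model, path) {
  p <- model$fit$params
  obj <- list(
    topology = list(n_in = nrow(model$factors), n_hidden = model$n_hidden,
                    n_out = 1L),
    params = list(hidden_weights = p$hidden_weights,
                  input_bias = p$input_bias,
                  output_weights = p$output_weights,
                  output_bias = p$output_bias),
    scaler_x = scaler_to_list(model$scaler_x),
    scaler_y = scaler_to_list(model$scaler_y),
    factors = as.list(model$factors),
    alpha = model$alpha,
    control = unclass(model$fit$control),
    final_sse = model$fit$final_sse,
    metrics = model$metrics
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  hw <- obj$params$hidden_weights
  if (!is.matrix(hw)) {  # row-wise list when a dimension is 1
    hw <- matrix(unlist(hw), obj$topology$n_hidden, obj$topology$n_in,
                 byrow = TRUE)
  }
  params <- structure(
    list(hidden_weights = hw,
         input_bias = as.numeric(obj$params$input_bias),
         output_weights = as.numeric(obj$params$output_weights),
         output_bias = as.numeric(obj$params$output_bias)),
    class = "ffnn_params"
  )
  fit <- structure(
    list(params = params, final_sse = obj$final_sse, epochs_run = NA_integer_,
         n_hidden = obj$topology$n_hidden, restarts = NULL,
         control = do.call(lm_control, obj$control)),
    class = "ffnn_fit"
  )
  structure(
    list(fit = fit,
         scaler_x = scaler_from_list(obj$scaler_x),
         scaler_y = scaler_from_list(obj$scaler_y),
         factors = as_tibble(obj$factors),
         alpha = obj$alpha,
         n_hidden = obj$topology$n_hidden,
         metrics = as_tibble(obj$metrics)),
    class = "activity_model"
  )
}
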