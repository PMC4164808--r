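#' Pairwise interaction surface of the fitted response
#'
#' Evaluates the trained network over a regular grid of two factors, with
#' every other factor held at its centre point (the response-surface
#' convention for interaction plots), and returns predicted activity in
#' U/mL in long format ready for contour or tile plotting.
#'
#' @param model An `activity_model`.
#' @param factor_i,factor_j Names of the two factors to vary (distinct).
#' @param resolution Number of equally spaced grid points per axis
#'   (default 25), spanning each factor's axial `[low, high]` range.
#' @param fixed Optional named numeric vector overriding the centre-point
#'   settings of the held-constant factors.
#' @return An `ffnn_surface` tibble with columns `<factor_i>`,
#'   `<factor_j>` and `activity_U_per_mL`, plus attributes `factor_i`,
#'   `factor_j` and `fixed_values`.
#' @examples
#' \donttest{
#' m <- fit_activity_model(alpha_gal_design(),
#'                         control = lm_control(n_restarts = 2, seed = 7))
#' s <- surface_grid(m, "tryptone_g_per_100mL", "temperature_C")
#' autoplot(s)
#' }
#' @export
surface_grid <- function(model, factor_i, factor_j, resolution = 25,
                         fixed = NULL) {
  factors <- model$factors
  check_that(factor_i %in% factors$name,
             sprintf("unknown factor '%s'", factor_i))
  check_that(factor_j %in% factors$name,
             sprintf("unknown factor '%s'", factor_j))
  check_that(factor_i != factor_j, "`factor_i` and `factor_j` must differ")
  check_that(resolution >= 2, "`resolution` must be >= 2")

  centre <- setNames((factors$low + factors$high) / 2, factors$name)
  if (!is.null(fixed)) {
    check_that(all(names(fixed) %in% factors$name),
               "`fixed` names must be factor names")
    centre[names(fixed)] <- fixed
  }
  axis_of <- function(nm) {
    i <- match(nm, factors$name)
    seq(factors$low[i], factors$high[i], length.out = resolution)
  }
  grid <- tidyr::expand_grid(..i = axis_of(factor_i), ..j = axis_of(factor_j))
  newdata <- as_tibble(as.data.frame(
    matrix(centre, nrow(grid), nrow(factors), byrow = TRUE,
           dimnames = list(NULL, factors$name))
  ))
  newdata[[factor_i]] <- grid$..i
  newdata[[factor_j]] <- grid$..j

  out <- tibble(!!factor_i := grid$..i, !!factor_j := grid$..j,
                activity_U_per_mL = predict(model, newdata))
  structure(out,
            factor_i = factor_i, factor_j = factor_j,
            fixed_values = centre[setdiff(factors$name, c(factor_i, factor_j))],
            class = c("ffnn_surface", class(tibble())))
}

#' All pairwise interaction surfaces
#'
#' Convenience wrapper computing [surface_grid()] for a set of factor
#' pairs (default: all pairs) and stacking them in one long tibble.
#'
#' @param model An `activity_model`.
#' @param pairs A list of length-2 character vectors of factor names, or
#'   `NULL` for every unordered pair.
#' @param resolution Grid points per axis.
#' @return A tibble with columns `factor_i`, `factor_j`, `value_i`,
#'   `value_j`, `activity_U_per_mL`.
#' @export
surface_grid_all <- function(model, pairs = NULL, resolution = 25) {
  nms <- model$factors$name
  if (is.null(pairs)) {
    idx <- utils::combn(nms, 2, simplify = FALSE)
  } else {
    idx <- pairs
  }
  purrr::map_dfr(idx, function(p) {
    s <- surface_grid(model, p[1], p[2], resolution)
    tibble(factor_i = p[1], factor_j = p[2],
           value_i = s[[p[1]]], value_j = s[[p[2]]],
           activity_U_per_mL = s$activity_U_per_mL)
  })
}

#' @rdname surface_grid
#' @param object An `ffnn_surface`.
#' @param ... Unused.
#' @method autoplot ffnn_surface
#' @export
autoplot.ffnn_surface <- function(object, ...) {
  fi <- attr(object, "factor_i")
  fj <- attr(object, "factor_j")
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[fi]], y = .data[[fj]],
                                       z = .data$activity_U_per_mL)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$activity_U_per_mL)) +
    ggplot2::geom_contour(colour = "white", alpha = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "activity\n(U/mL)") +
    ggplot2::labs(x = fi, y = fj,
                  title = "Predicted activity, other factors at centre")
}
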