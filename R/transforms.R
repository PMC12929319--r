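#' Transform specification for bounded utilities
#'
#' EQ-5D-3L utilities scored with the French tariff live on
#' \eqn{[u_{min}, u_{max}] = [-0.53, 1.00]}. Beta-family models work on the
#' rescaled decrement \eqn{y = (u_{max} - u) / (u_{max} - u_{min})}, a shortfall
#' from full health in \eqn{[0, 1]}, compressed strictly inside the open unit
#' interval before a beta density is applied. A `transform_spec` carries the
#' bounds and the compression sample size.
#'
#' @param u_min Lower bound of attainable utilities (worst health state).
#' @param u_max Upper bound of attainable utilities (full health).
#' @param n_obs Number of observations used for boundary compression;
#'   must be at least 2. May be `NULL` when compression is not needed yet.
#' @return An object of class `transform_spec`.
#' @examples
#' spec <- transform_spec(n_obs = 5679)
#' rescale_to_decrement(0.235, spec)
#' @export
transform_spec <- function(u_min = -0.53, u_max = 1.00, n_obs = NULL) {
  if (!is.numeric(u_min) || !is.numeric(u_max) || u_min >= u_max) {
    abort("`u_min` must be strictly less than `u_max`.", class = "hsuv_config_error")
  }
  if (!is.null(n_obs)) {
    n_obs <- as.integer(n_obs)
    if (is.na(n_obs) || n_obs < 2) {
      abort("Compression requires `n_obs` >= 2.", class = "hsuv_config_error")
    }
  }
  structure(list(u_min = u_min, u_max = u_max, n_obs = n_obs),
            class = "transform_spec")
}

#' Rescale utilities to decrements in [0, 1]
#'
#' Maps a utility `u` to the decrement `y = (u_max - u) / (u_max - u_min)`,
#' so `y = 0` is full health and `y = 1` the worst attainable state.
#'
#' @param u Numeric vector of utilities in `[u_min, u_max]`.
#' @param spec A [transform_spec()].
#' @return Numeric vector of decrements in `[0, 1]`.
#' @export
rescale_to_decrement <- function(u, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  bad <- !is.na(u) & (u < spec$u_min - 1e-12 | u > spec$u_max + 1e-12)
  if (any(bad)) {
    abort(sprintf("%d utilit%s outside [%g, %g].", sum(bad),
                  if (sum(bad) == 1) "y" else "ies", spec$u_min, spec$u_max),
          class = "hsuv_range_error")
  }
  pmin(pmax((spec$u_max - u) / (spec$u_max - spec$u_min), 0), 1)
}

#' Compress decrements strictly inside (0, 1)
#'
#' Applies `y* = (y * (N - 1) + 0.5) / N`, pulling exact boundary values
#' strictly inside the open unit interval so a beta density can be evaluated.
#' The map is strictly increasing with fixed point 0.5.
#'
#' @param y Numeric vector of decrements in `[0, 1]`.
#' @param n_obs Total number of observations `N`; defaults to the
#'   transform object's `n_obs`, else `length(y)`.
#' @inheritParams rescale_to_decrement
#' @return Numeric vector in the open interval (0, 1).
#' @export
compress_decrement <- function(y, spec = transform_spec(), n_obs = NULL) {
  n <- n_obs %||% spec$n_obs %||% length(y)
  if (n < 2) abort("Compression requires N >= 2.", class = "hsuv_config_error")
  if (any(!is.na(y) & (y < -1e-12 | y > 1 + 1e-12))) {
    abort("Decrements must lie in [0, 1].", class = "hsuv_range_error")
  }
  (y * (n - 1) + 0.5) / n
}

#' Back-transform predicted decrements to the utility scale
#'
#' Inverse of [rescale_to_decrement()]: `u = u_max - y * (u_max - u_min)`.
#'
#' @param y_hat Numeric vector of predicted decrements in `[0, 1]`.
#' @inheritParams rescale_to_decrement
#' @return Numeric vector of utilities in `[u_min, u_max]`.
#' @export
back_transform <- function(y_hat, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.na(y_hat) & (y_hat < -1e-12 | y_hat > 1 + 1e-12))) {
    abort("Predicted decrements must lie in [0, 1].", class = "hsuv_range_error")
  }
  spec$u_max - y_hat * (spec$u_max - spec$u_min)
}

#' Invert the boundary compression
#'
#' Maps a compressed decrement back through `y = (y* N - 0.5) / (N - 1)`,
#' clamped to `[y_min, 1]`. Used by the synthetic-data generator, which draws
#' beta variates on the compression scale the likelihood is defined on and
#' emits the corresponding raw decrements.
#'
#' @param y_star Values in (0, 1).
#' @param n_obs Compression sample size `N`.
#' @param y_min Lower clamp for the result (0 permits exact full health).
#' @return Numeric vector of raw decrements.
#' @export
decompress_decrement <- function(y_star, n_obs, y_min = 0) {
  pmin(pmax((y_star * n_obs - 0.5) / (n_obs - 1), y_min), 1)
}

#' Piecewise-linear time basis split at one year post-transplantation
#'
#' Follow-up time is decomposed as `t_pre = min(t, knot)` and
#' `t_post = max(t - knot, 0)`, giving one utility slope for the acute first
#' year after transplantation and another for the chronic phase thereafter.
#' The basis is continuous at the knot and `t_pre + t_post = t`.
#'
#' @param t Numeric vector of years since transplantation (non-negative).
#' @param knot Changepoint in years; default 1.
#' @return A tibble with columns `t_pre` and `t_post`.
#' @examples
#' time_basis(c(0.5, 1, 5))
#' @export
time_basis <- function(t, knot = 1) {
  if (any(!is.na(t) & t < 0)) {
    abort("Times since transplantation must be non-negative.",
          class = "hsuv_range_error")
  }
  tibble::tibble(t_pre = pmin(t, knot), t_post = pmax(t - knot, 0))
}
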