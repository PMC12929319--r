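# Prediction of utilities from fitted models, on the HSUV scale.

predictor_matrix <- function(object, newdata) {
  newdata <- tibble::as_tibble(newdata)
  miss <- setdiff(c(object$covariates, "time"), names(newdata))
  if (length(miss)) {
    abort(paste0("`newdata` lacks column(s): ", paste(miss, collapse = ", ")),
          class = "hsuv_data_error")
  }
  if (any(newdata$time < 0)) {
    abort("Prediction times must be non-negative.", class = "hsuv_range_error")
  }
  tb <- time_basis(newdata$time, knot = object$knot)
  X <- cbind(`(Intercept)` = 1, as.matrix(newdata[object$covariates]),
             t_pre = tb$t_pre, t_post = tb$t_post)
  storage.mode(X) <- "double"
  list(X = X, tpre = tb$t_pre)
}

aldvmm_censored_mean <- function(mean_c, sigma, psi1, u_min, u_max) {
  a <- (u_min - mean_c) / sigma
  b <- (psi1 - mean_c) / sigma
  u_min * pnorm(a) + u_max * pnorm(b, lower.tail = FALSE) +
    mean_c * (pnorm(b) - pnorm(a)) - sigma * (dnorm(b) - dnorm(a))
}

#' Predict health-state utility values
#'
#' Computes predicted HSUVs for new covariate/time rows, on the utility
#' scale and clamped to `[u_min, u_max]`. `mode = "conditional_b0"` sets the
#' random effects to zero (the population-typical patient, the scale on
#' which precision metrics are reported); `mode = "marginal"` averages the
#' outcome mean over the random-effect distribution by Gauss-Hermite
#' quadrature (identical for the linear model, where the mean is linear in
#' the random effects).
#'
#' @param object An `hsuv_fit`.
#' @param newdata Data frame with the model covariates and a `time` column.
#' @param mode `"conditional_b0"` or `"marginal"`.
#' @param ... Unused.
#' @return Numeric vector of predicted utilities.
#' @export
predict.hsuv_fit <- function(object, newdata,
                             mode = c("conditional_b0", "marginal"), ...) {
  mode <- match.arg(mode)
  pm <- predictor_matrix(object, newdata)
  spec <- object$spec
  fam <- object$family
  if (mode == "marginal") {
    sds <- c(object$sd_intercept %||% 0, object$sd_slope %||% 0,
             object$sd_zero_intercept %||% 0)
    if (all(sds < 1e-8)) {
      warn("Degenerate random-effect variance; falling back to conditional_b0.")
      mode <- "conditional_b0"
    }
  }
  pred <- switch(fam,
    lmm = as.numeric(pm$X %*% object$beta[colnames(pm$X)]),
    beta = {
      eta <- as.numeric(pm$X %*% object$beta[colnames(pm$X)])
      mu <- if (mode == "conditional_b0") plogis(eta) else
        gauss_mean_2d(eta, pm$tpre, object$sd_intercept,
                      object$sd_slope %||% 0, plogis, object$nodes)
      back_transform(mu, spec)
    },
    twopart_beta = {
      eta_z <- as.numeric(pm$X %*% object$gamma[colnames(pm$X)])
      eta <- as.numeric(pm$X %*% object$beta[colnames(pm$X)])
      if (mode == "conditional_b0") {
        p0 <- plogis(eta_z)
        mu <- plogis(eta)
      } else {
        p0 <- gauss_mean_1d(eta_z, object$sd_zero_intercept, plogis,
                            object$nodes)
        mu <- gauss_mean_2d(eta, pm$tpre, object$sd_intercept,
                            object$sd_slope %||% 0, plogis, object$nodes)
      }
      back_transform((1 - p0) * mu, spec)
    },
    aldvmm = {
      K <- length(object$pi)
      eta <- pm$X %*% t(object$beta[, colnames(pm$X), drop = FALSE])
      mean_fun <- function(b) {
        acc <- 0
        for (c in seq_len(K)) {
          acc <- acc + object$pi[c] *
            aldvmm_censored_mean(eta[, c] + b, object$sigma[c],
                                 object$psi1, spec$u_min, spec$u_max)
        }
        acc
      }
      if (mode == "conditional_b0") mean_fun(0) else {
        rule <- gh_rule(object$nodes)
        w <- exp(rule$logw - rule$x^2); w <- w / sum(w)
        b_nodes <- sqrt(2) * object$sd_intercept * rule$x
        Reduce(`+`, lapply(seq_along(b_nodes),
                           function(k) w[k] * mean_fun(b_nodes[k])))
      }
    })
  pmin(pmax(pred, spec$u_min), spec$u_max)
}

# E[g(eta + b0)] over b0 ~ N(0, tau^2), vectorized over eta
gauss_mean_1d <- function(eta, tau, g, nodes) {
  if (tau < 1e-8) return(g(eta))
  rule <- gh_rule(nodes)
  w <- exp(rule$logw - rule$x^2); w <- w / sum(w)
  b <- sqrt(2) * tau * rule$x
  out <- 0
  for (k in seq_along(b)) out <- out + w[k] * g(eta + b[k])
  out
}

# E[g(eta + b0 + b1 * tpre)] over independent b0, b1
gauss_mean_2d <- function(eta, tpre, tau0, tau1, g, nodes) {
  if (tau1 < 1e-8) return(gauss_mean_1d(eta, tau0, g, nodes))
  rule <- gh_rule(nodes)
  w <- exp(rule$logw - rule$x^2); w <- w / sum(w)
  b0 <- sqrt(2) * tau0 * rule$x
  b1 <- sqrt(2) * tau1 * rule$x
  out <- 0
  for (ka in seq_along(b0)) {
    for (kb in seq_along(b1)) {
      out <- out + w[ka] * w[kb] * g(eta + b0[ka] + b1[kb] * tpre)
    }
  }
  out
}

#' Predict utility trajectories over a time grid
#'
#' Evaluates predicted HSUVs for each profile row at each time in `times`,
#' returning a tidy table suitable for plotting or QALY integration.
#'
#' @param object An `hsuv_fit` (or a model reloaded with
#'   [read_hsuv_model()]).
#' @param profiles Data frame of covariate rows (one per patient profile).
#' @param times Numeric vector of years since transplantation.
#' @param mode Prediction mode, as in [predict.hsuv_fit()].
#' @return A tibble with columns `profile`, `time`, `hsuv_pred`.
#' @export
predict_trajectory <- function(object, profiles,
                               times = seq(0, 10, by = 0.25),
                               mode = "conditional_b0") {
  profiles <- tibble::as_tibble(profiles)
  profiles$profile <- seq_len(nrow(profiles))
  grid <- tidyr::crossing(profiles, time = times)
  grid$hsuv_pred <- predict(object, grid, mode = mode)
  cls <- class(grid)
  out <- grid[c("profile", "time", "hsuv_pred")]
  structure(out, class = c("hsuv_trajectory", class(out)))
}

#' Quality-adjusted life-years from a utility trajectory
#'
#' Trapezoidal integration of predicted HSUVs over time, per profile: the
#' QALY contribution of the spanned interval. A constant utility `u` over
#' one year contributes `u` QALYs.
#'
#' @param trajectory Output of [predict_trajectory()], or any data frame
#'   with `profile`, `time` and `hsuv_pred` columns.
#' @return A tibble with columns `profile`, `from`, `to`, `qaly`.
#' @export
qaly <- function(trajectory) {
  trajectory |>
    dplyr::group_by(.data$profile) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::summarise(
      from = min(.data$time), to = max(.data$time),
      qaly = sum(diff(.data$time) *
                   (head(.data$hsuv_pred, -1) + tail(.data$hsuv_pred, -1)) / 2),
      .groups = "drop")
}
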