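#' @export
print.hsuv_fit <- function(x, ...) {
  cat("Longitudinal utility model (", x$family, ")\n", sep = "")
  cat(sprintf("  %d patients, %d questionnaires", x$n_patients, x$n_obs))
  if (x$n_dropped_rows > 0) {
    cat(sprintf("  [%d rows dropped, %d patients excluded for missing data]",
                x$n_dropped_rows, x$n_dropped_patients))
  }
  cat("\n")
  cat(sprintf("  logLik %.3f | AIC %.1f | BIC %.1f | %d parameters\n",
              x$loglik, x$aic, x$bic, x$n_par))
  print(tidy(x), n = 30)
  invisible(x)
}

#' Tidy a fitted utility model
#'
#' One row per estimated parameter: fixed effects, variance components and,
#' for the two-part model, both parts (`component` column). Confidence
#' intervals are Wald intervals on the estimation scale.
#'
#' @param x An `hsuv_fit`.
#' @param conf_level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @method tidy hsuv_fit
#' @export
tidy.hsuv_fit <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  row_block <- function(component, term, est, se) {
    tibble::tibble(component = component, term = term, estimate = est,
                   std.error = se,
                   conf.low = est - z * se, conf.high = est + z * se)
  }
  na_like <- function(v) rep(NA_real_, length(v))
  out <- switch(x$family,
    lmm = dplyr::bind_rows(
      row_block("mean", names(x$beta), unname(x$beta),
                unname(x$beta_se %||% na_like(x$beta))),
      row_block("varcomp",
                c("sd_intercept",
                  if (!is.null(x$sd_slope)) "sd_slope", "sd_resid"),
                c(x$sd_intercept, x$sd_slope, x$sd_resid),
                unname(x$varcomp_se %||% na_like(1:(2 + !is.null(x$sd_slope)))))),
    beta = dplyr::bind_rows(
      row_block("mean", names(x$beta), unname(x$beta),
                unname(x$beta_se %||% na_like(x$beta))),
      row_block("varcomp",
                c("phi", "sd_intercept", if (!is.null(x$sd_slope)) "sd_slope"),
                c(x$phi, x$sd_intercept, x$sd_slope),
                unname(x$varcomp_se %||% na_like(1:(2 + !is.null(x$sd_slope)))))),
    twopart_beta = dplyr::bind_rows(
      row_block("zero", names(x$gamma), unname(x$gamma),
                unname(x$gamma_se %||% na_like(x$gamma))),
      row_block("zero", "sd_zero_intercept", x$sd_zero_intercept,
                unname(x$varcomp_se["sd_zero_intercept"] %||% NA_real_)),
      row_block("conditional", names(x$beta), unname(x$beta),
                unname(x$beta_se %||% na_like(x$beta))),
      row_block("conditional",
                c("phi", "sd_intercept", if (!is.null(x$sd_slope)) "sd_slope"),
                c(x$phi, x$sd_intercept, x$sd_slope),
                unname(x$varcomp_se[c("phi", "sd_intercept",
                                      if (!is.null(x$sd_slope)) "sd_slope")] %||%
                         na_like(1:(2 + !is.null(x$sd_slope)))))),
    aldvmm = {
      K <- length(x$pi)
      blocks <- lapply(seq_len(K), function(c) {
        se_c <- if (!is.null(x$beta_se)) unname(x$beta_se[c, ]) else
          na_like(x$beta[c, ])
        row_block(paste0("class", c), colnames(x$beta),
                  unname(x$beta[c, ]), se_c)
      })
      dplyr::bind_rows(
        dplyr::bind_rows(blocks),
        row_block("varcomp",
                  c(paste0("sigma_class", seq_len(K)),
                    if (K > 1) paste0("pi_class", seq_len(K)),
                    "sd_intercept"),
                  c(x$sigma, if (K > 1) x$pi, x$sd_intercept),
                  na_like(seq_len(K + (K > 1) * K + 1))))
    })
  out
}

#' One-line model summary
#'
#' @param x An `hsuv_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit statistics.
#' @method glance hsuv_fit
#' @export
glance.hsuv_fit <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    logLik = x$loglik, AIC = x$aic, BIC = x$bic,
    n_par = x$n_par, nobs = x$n_obs, n_patients = x$n_patients,
    n_dropped_rows = x$n_dropped_rows,
    converged = x$convergence$code == 0 ||
      isTRUE(x$convergence$acceptable))
}

#' @export
logLik.hsuv_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_par, nobs = object$n_obs,
            class = "logLik")
}

#' Information criteria of a fitted utility model
#'
#' AIC and BIC with the number of questionnaires as the BIC sample size,
#' the criterion used to choose the number of ALDVMM classes.
#'
#' @param fit An `hsuv_fit`.
#' @return A one-row tibble with `logLik`, `n_par`, `AIC`, `BIC`.
#' @export
information_criteria <- function(fit) {
  tibble::tibble(logLik = fit$loglik, n_par = fit$n_par,
                 AIC = fit$aic, BIC = fit$bic)
}
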