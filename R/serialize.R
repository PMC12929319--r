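# JSON serialization of fitted models, so the prediction engine (and a
# downstream calculator UI) can reload a fit without refitting.

#' Write a fitted model to JSON
#'
#' Stores family, covariate coding, coefficients, variance components,
#' transform constants and fit diagnostics in a documented JSON layout.
#' The reloaded object supports prediction but not re-optimization.
#'
#' @param fit An `hsuv_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hsuv_model <- function(fit, path) {
  payload <- list(
    schema = "hsuvlong-model/1",
    family = fit$family,
    covariates = fit$covariates,
    knot = fit$knot,
    nodes = fit$nodes,
    re_slope = fit$re_slope,
    center_age = fit$center_age,
    transform = list(u_min = fit$spec$u_min, u_max = fit$spec$u_max,
                     n_obs = fit$spec$n_obs),
    coefficients = list(
      beta = if (is.matrix(fit$beta)) {
        list(matrix = unname(as.list(as.data.frame(t(fit$beta)))),
             names = colnames(fit$beta))
      } else as.list(fit$beta),
      gamma = if (!is.null(fit$gamma)) as.list(fit$gamma)),
    varcomp = list(sd_intercept = fit$sd_intercept,
                   sd_slope = fit$sd_slope,
                   sd_resid = fit$sd_resid,
                   sd_zero_intercept = fit$sd_zero_intercept,
                   phi = fit$phi, sigma = fit$sigma, pi = fit$pi,
                   psi1 = fit$psi1),
    fit_stats = list(loglik = fit$loglik, n_par = fit$n_par,
                     aic = fit$aic, bic = fit$bic, n_obs = fit$n_obs,
                     n_patients = fit$n_patients),
    convergence = fit$convergence[c("code", "message", "iterations")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path Path written by [write_hsuv_model()].
#' @return An `hsuv_fit` usable with [predict.hsuv_fit()], [tidy()] and
#'   [glance()].
#' @export
read_hsuv_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "hsuvlong-model/1")) {
    abort("Not an hsuvlong model file.", class = "hsuv_parse_error")
  }
  beta <- p$coefficients$beta
  if (!is.null(beta$matrix)) {
    B <- beta$matrix
    if (is.list(B)) B <- do.call(rbind, B)
    B <- as.matrix(B)
    colnames(B) <- beta$names
    beta <- B
  } else {
    beta <- unlist(beta)
  }
  fit <- list(
    family = p$family, covariates = p$covariates, knot = p$knot,
    nodes = p$nodes, re_slope = p$re_slope,
    center_age = isTRUE(p$center_age),
    spec = transform_spec(p$transform$u_min, p$transform$u_max,
                          p$transform$n_obs),
    beta = beta,
    gamma = if (!is.null(p$coefficients$gamma)) unlist(p$coefficients$gamma),
    sd_intercept = p$varcomp$sd_intercept,
    sd_slope = p$varcomp$sd_slope,
    sd_resid = p$varcomp$sd_resid,
    sd_zero_intercept = p$varcomp$sd_zero_intercept,
    phi = p$varcomp$phi, sigma = p$varcomp$sigma, pi = p$varcomp$pi,
    psi1 = p$varcomp$psi1,
    loglik = p$fit_stats$loglik, n_par = p$fit_stats$n_par,
    aic = p$fit_stats$aic, bic = p$fit_stats$bic,
    n_obs = p$fit_stats$n_obs, n_patients = p$fit_stats$n_patients,
    n_dropped_rows = 0L, n_dropped_patients = 0L,
    convergence = as.list(p$convergence))
  structure(fit, class = "hsuv_fit")
}

#' Read a long-format cohort CSV
#'
#' Expected columns: `patient_id`, `time`, and either `hsuv` or a 5-digit
#' `profile` column (scored on read when a value set is given), plus
#' covariates.
#'
#' @param path CSV path.
#' @param value_set Optional [value_set()] used to score a `profile` column.
#' @return A tibble.
#' @export
read_cohort <- function(path, value_set = NULL) {
  data <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("patient_id", "time") %in% names(data))) {
    abort("Cohort CSV needs `patient_id` and `time` columns.",
          class = "hsuv_data_error")
  }
  if (!"hsuv" %in% names(data)) {
    if (is.null(value_set)) {
      abort("Cohort CSV has no `hsuv` column and no value set was given.",
            class = "hsuv_data_error")
    }
    data <- score_eq5d(data, value_set)
  }
  data
}

#' Write a cohort to CSV
#'
#' @param data Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
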