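#' Per-observation conditional log-density given the random effects
#'
#' Family dispatch for the conditional (given random effect `b`) log-density
#' of a single questionnaire outcome:
#' * `lmm`: normal density of `u` around `eta + b` with SD `sd_resid`;
#' * `beta`: beta density of the compressed decrement with mean
#'   `plogis(eta + b)` and precision `phi` (the decrement is computed from
#'   `u` and compressed using `spec$n_obs`);
#' * `twopart_beta`: if the raw decrement is 0, `log P0` with
#'   `P0 = plogis(eta_zero + b_zero)`; else `log(1 - P0)` plus the beta
#'   density of the compressed positive decrement;
#' * `aldvmm`: log of the mixture density with censoring masses at the
#'   boundaries; component means are `eta + b` per class.
#'
#' @param u Utility value(s).
#' @param eta Linear predictor(s) on the family's modelling scale. For
#'   `aldvmm` a vector/matrix of per-class means; for `twopart_beta` supply
#'   the conditional-part predictor here and the zero-part predictor via
#'   `eta_zero`.
#' @param family Model family.
#' @param params Family parameters (`sd_resid`, or `phi`, or `pi`/`sigma`/
#'   `psi1`).
#' @param b Random-effect value added to `eta` (default 0).
#' @param b_zero Random-effect value added to `eta_zero` (default 0).
#' @param eta_zero Zero-part linear predictor (two-part family only).
#' @param spec A [transform_spec()]; its `n_obs` drives the compression used
#'   by the beta families.
#' @return Vector of per-observation log-densities.
#' @export
obs_loglik_conditional <- function(u, eta, family, params, b = 0,
                                   b_zero = 0, eta_zero = NULL,
                                   spec = transform_spec(n_obs = length(u))) {
  if (any(u < spec$u_min - 1e-9 | u > spec$u_max + 1e-9)) {
    abort("Utilities outside the transform bounds.", class = "hsuv_data_error")
  }
  switch(family,
    lmm = {
      if (params$sd_resid <= 0) abort("sd_resid must be > 0.",
                                      class = "hsuv_param_error")
      dnorm(u, eta + b, params$sd_resid, log = TRUE)
    },
    beta = {
      if (params$phi <= 0) abort("phi must be > 0.",
                                 class = "hsuv_param_error")
      y_star <- compress_decrement(rescale_to_decrement(u, spec), spec)
      mu <- plogis(eta + b)
      dbeta(y_star, mu * params$phi, (1 - mu) * params$phi, log = TRUE)
    },
    twopart_beta = {
      if (params$phi <= 0) abort("phi must be > 0.",
                                 class = "hsuv_param_error")
      if (is.null(eta_zero)) abort("Two-part family needs `eta_zero`.",
                                   class = "hsuv_param_error")
      y <- rescale_to_decrement(u, spec)
      is_zero <- y < 1e-12
      p0 <- plogis(eta_zero + b_zero)
      out <- numeric(length(u))
      out[is_zero] <- log(p0[is_zero])
      if (any(!is_zero)) {
        n_pos <- spec$n_obs %||% sum(!is_zero)
        y_star <- compress_decrement(y[!is_zero], n_obs = n_pos)
        mu <- plogis((eta + b)[!is_zero])
        out[!is_zero] <- log1p(-p0[!is_zero]) +
          dbeta(y_star, mu * params$phi, (1 - mu) * params$phi, log = TRUE)
      }
      out
    },
    aldvmm = {
      if (any(params$sigma <= 0)) abort("sigma must be > 0.",
                                        class = "hsuv_param_error")
      eta_m <- if (is.matrix(eta)) eta else matrix(eta, length(u),
                                                   length(params$pi))
      aldvmm_obs_ll(u, eta_m + b, params$pi, params$sigma, params$psi1,
                    spec$u_min, spec$u_max)
    },
    abort(paste0("Unknown family: ", family), class = "hsuv_config_error"))
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Evaluates the marginal log-likelihood of a cohort under given parameters
#' for any of the four families, integrating the patient random effects
#' numerically (adaptive Gauss-Hermite, `nodes` nodes per dimension). For
#' the `lmm` family this is the quadrature counterpart of
#' [loglik_lmm_closed_form()] and agrees with it to near machine precision.
#'
#' @inheritParams fit_hsuv
#' @param params Parameter list for the family (see `default_*_params()`).
#' @return The marginal log-likelihood (scalar).
#' @export
loglik_marginal_quadrature <- function(data, params,
                                       family = params$family,
                                       covariates = NULL, nodes = 9,
                                       u_min = -0.53, u_max = 1.00,
                                       knot = 1) {
  check_params(params, family)
  covariates <- covariates %||% {
    cn <- if (family == "aldvmm") colnames(params$beta) else
      names(params$beta %||% params$gamma)
    setdiff(cn, c("(Intercept)", "t_pre", "t_post"))
  }
  spec <- transform_spec(u_min, u_max)
  mf <- build_model_frame(data, covariates, knot = knot, spec = spec,
                          check_range = family != "lmm")
  rule <- gh_rule(nodes)
  re_sd <- function(x) max(x %||% 0, 0)

  if (family == "lmm") {
    fam <- fam_gaussian(mf$u, params$sd_resid)
    eta <- as.numeric(mf$X %*% params$beta[colnames(mf$X)])
    tau1 <- re_sd(params$sd_slope)
    ll <- if (tau1 > 0) {
      agh_loglik_2d(fam, eta, mf$tpre, mf$pid, mf$m, params$sd_intercept,
                    tau1, rule)
    } else {
      agh_loglik_1d(fam, eta, mf$pid, mf$m, params$sd_intercept, rule)
    }
    return(sum(ll))
  }
  if (family == "beta") {
    y_star <- compress_decrement(rescale_to_decrement(mf$u, spec),
                                 n_obs = mf$n)
    fam <- fam_beta(y_star, params$phi)
    eta <- as.numeric(mf$X %*% params$beta[colnames(mf$X)])
    tau1 <- re_sd(params$sd_slope)
    ll <- if (tau1 > 0) {
      agh_loglik_2d(fam, eta, mf$tpre, mf$pid, mf$m, params$sd_intercept,
                    tau1, rule)
    } else {
      agh_loglik_1d(fam, eta, mf$pid, mf$m, params$sd_intercept, rule)
    }
    return(sum(ll))
  }
  if (family == "twopart_beta") {
    zero <- abs(mf$u - spec$u_max) < 1e-8
    z <- as.integer(zero)
    eta_z <- as.numeric(mf$X %*% params$gamma[colnames(mf$X)])
    ll_zero <- agh_loglik_1d(fam_bernoulli(z), eta_z, mf$pid, mf$m,
                             params$sd_zero_intercept, rule)
    keep <- !zero
    ll_cond <- 0
    if (any(keep)) {
      y_pos <- rescale_to_decrement(mf$u[keep], spec)
      y_star <- compress_decrement(y_pos, n_obs = sum(keep))
      pid_pos <- match(mf$pid[keep], unique(mf$pid[keep]))
      fam <- fam_beta(y_star, params$phi)
      eta <- as.numeric((mf$X %*% params$beta[colnames(mf$X)])[keep])
      tau1 <- re_sd(params$sd_slope)
      ll_cond <- if (tau1 > 0) {
        agh_loglik_2d(fam, eta, mf$tpre[keep], pid_pos, max(pid_pos),
                      params$sd_intercept, tau1, rule)
      } else {
        agh_loglik_1d(fam, eta, pid_pos, max(pid_pos),
                      params$sd_intercept, rule)
      }
    }
    return(sum(ll_zero) + sum(ll_cond))
  }
  # aldvmm
  eta <- mf$X %*% t(params$beta[, colnames(mf$X), drop = FALSE])
  ll_off <- function(b_off) {
    if (is.matrix(b_off)) {
      out <- matrix(NA_real_, nrow(b_off), ncol(b_off))
      for (j in seq_len(ncol(b_off))) {
        out[, j] <- aldvmm_obs_ll(mf$u, eta + b_off[, j], params$pi,
                                  params$sigma, params$psi1,
                                  spec$u_min, spec$u_max)
      }
      out
    } else {
      aldvmm_obs_ll(mf$u, eta + b_off, params$pi, params$sigma,
                    params$psi1, spec$u_min, spec$u_max)
    }
  }
  fam <- numeric_derivs(ll_off)
  sum(agh_loglik_1d(fam, numeric(mf$n), mf$pid, mf$m,
                    params$sd_intercept, rule))
}
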