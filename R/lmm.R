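# Closed-form marginal likelihood of the Gaussian linear mixed model with a
# patient random intercept and (optionally) an independent random slope on
# t_pre. The per-patient covariance is sigma^2 I + Z D Z'; all per-patient
# quantities reduce, via the Woodbury identity, to small sufficient
# statistics that are vectorized across patients, so one likelihood
# evaluation is O(total observations) with no explicit loop. The fixed
# effects are profiled out by generalized least squares, leaving a 2- or
# 3-parameter optimization over log variance components.

lmm_suffstats <- function(mf) {
  pid <- mf$pid; X <- mf$X; y <- mf$u; tp <- mf$tpre
  list(
    s11 = as.numeric(rowsum(rep(1, mf$n), pid, reorder = TRUE)),
    s12 = as.numeric(rowsum(tp, pid, reorder = TRUE)),
    s22 = as.numeric(rowsum(tp^2, pid, reorder = TRUE)),
    U1 = rowsum(X, pid, reorder = TRUE),
    U2 = rowsum(X * tp, pid, reorder = TRUE),
    zy1 = as.numeric(rowsum(y, pid, reorder = TRUE)),
    zy2 = as.numeric(rowsum(y * tp, pid, reorder = TRUE)),
    XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2)
  )
}

# Profiled -2 log-likelihood pieces for variance components (tau0, tau1,
# sigma); tau1 = NULL drops the random slope. Returns the GLS beta-hat, its
# information matrix A = X' Sigma^-1 X, and the maximized log-likelihood for
# these variance components.
lmm_profile_eval <- function(ss, n, m, tau0, tau1, sigma) {
  sig2 <- sigma^2
  if (is.null(tau1)) {
    g <- sig2 / tau0^2 + ss$s11
    i11 <- 1 / g
    SXZ <- crossprod(ss$U1, ss$U1 * i11)
    cz <- crossprod(ss$U1, i11 * ss$zy1)
    qz <- sum(i11 * ss$zy1^2)
    logdet <- sum((ss$s11 - 1) * log(sig2)) + sum(log(g)) + m * log(tau0^2)
  } else {
    g11 <- sig2 / tau0^2 + ss$s11
    g12 <- ss$s12
    g22 <- sig2 / tau1^2 + ss$s22
    det_g <- g11 * g22 - g12^2
    i11 <- g22 / det_g; i12 <- -g12 / det_g; i22 <- g11 / det_g
    SXZ <- crossprod(ss$U1, ss$U1 * i11 + ss$U2 * i12) +
      crossprod(ss$U2, ss$U1 * i12 + ss$U2 * i22)
    cz <- crossprod(ss$U1, i11 * ss$zy1 + i12 * ss$zy2) +
      crossprod(ss$U2, i12 * ss$zy1 + i22 * ss$zy2)
    qz <- sum(i11 * ss$zy1^2 + 2 * i12 * ss$zy1 * ss$zy2 + i22 * ss$zy2^2)
    logdet <- sum((ss$s11 - 2) * log(sig2)) + sum(log(det_g)) +
      m * (log(tau0^2) + log(tau1^2))
  }
  A <- (ss$XtX - SXZ) / sig2
  cvec <- (ss$Xty - cz) / sig2
  q <- (ss$yty - qz) / sig2
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  beta <- backsolve(ch, forwardsolve(t(ch), cvec))
  quad <- q - sum(cvec * beta)
  ll <- -0.5 * (n * log(2 * pi) + logdet + quad)
  list(ll = ll, beta = as.numeric(beta), A = A)
}

fit_lmm_internal <- function(mf, re_slope = TRUE, start = NULL,
                             compute_se = TRUE) {
  ss <- lmm_suffstats(mf)
  p <- ncol(mf$X)
  sd_y <- sd(mf$u)
  lb <- log(1e-4); ub <- log(5)
  if (re_slope) {
    start <- start %||% log(c(0.6 * sd_y, 0.3 * sd_y, 0.7 * sd_y))
    obj <- function(th) {
      ev <- lmm_profile_eval(ss, mf$n, mf$m, exp(th[1]), exp(th[2]), exp(th[3]))
      if (is.null(ev) || !is.finite(ev$ll)) return(1e10)
      -ev$ll
    }
  } else {
    start <- start %||% log(c(0.6 * sd_y, 0.7 * sd_y))
    obj <- function(th) {
      ev <- lmm_profile_eval(ss, mf$n, mf$m, exp(th[1]), NULL, exp(th[2]))
      if (is.null(ev) || !is.finite(ev$ll)) return(1e10)
      -ev$ll
    }
  }
  opt <- nlminb(start, obj, lower = lb, upper = ub,
                control = list(iter.max = 400, eval.max = 800))
  th <- opt$par
  if (re_slope) {
    tau0 <- exp(th[1]); tau1 <- exp(th[2]); sigma <- exp(th[3])
    ev <- lmm_profile_eval(ss, mf$n, mf$m, tau0, tau1, sigma)
  } else {
    tau0 <- exp(th[1]); tau1 <- NULL; sigma <- exp(th[2])
    ev <- lmm_profile_eval(ss, mf$n, mf$m, tau0, NULL, sigma)
  }
  beta <- setNames(ev$beta, colnames(mf$X))
  vc_se <- rep(NA_real_, length(th))
  beta_se <- rep(NA_real_, p)
  if (compute_se) {
    beta_se <- sqrt(diag(solve(ev$A)))
    H <- tryCatch(optimHess(th, obj), error = function(e) NULL)
    if (!is.null(H)) {
      vc_log_se <- tryCatch(sqrt(diag(solve(H))), error = function(e)
        rep(NA_real_, length(th)))
      vc_se <- exp(th) * vc_log_se   # delta method back to the SD scale
    }
  }
  n_par <- p + length(th)
  list(
    beta = beta, beta_se = setNames(beta_se, colnames(mf$X)),
    sd_intercept = tau0,
    sd_slope = if (re_slope) tau1 else NULL,
    sd_resid = sigma,
    varcomp_se = setNames(vc_se, if (re_slope)
      c("sd_intercept", "sd_slope", "sd_resid") else
        c("sd_intercept", "sd_resid")),
    loglik = ev$ll, n_par = n_par,
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       objective = opt$objective)
  )
}

#' Closed-form marginal log-likelihood of the linear mixed model
#'
#' Evaluates the exact Gaussian marginal log-likelihood of utilities under a
#' linear mixed model with given fixed effects and variance components
#' (random intercept, optional independent random slope on `t_pre`, residual
#' SD), integrating the random effects analytically per patient. Serves as
#' the closed-form oracle against which the quadrature path is checked.
#'
#' @param data Long-format cohort data (see [simulate_cohort()] for schema).
#' @param params Parameter list with `beta` (named coefficient vector
#'   covering intercept, covariates, `t_pre`, `t_post`), `sd_intercept`,
#'   optional `sd_slope`, and `sd_resid`.
#' @param covariates Character vector of covariate column names; defaults to
#'   the covariate names present in `params$beta`.
#' @param knot Time-basis changepoint (years).
#' @return The marginal log-likelihood (scalar).
#' @export
loglik_lmm_closed_form <- function(data, params, covariates = NULL, knot = 1) {
  covariates <- covariates %||%
    setdiff(names(params$beta), c("(Intercept)", "t_pre", "t_post"))
  mf <- build_model_frame(data, covariates, knot = knot, check_range = FALSE)
  beta <- params$beta[coef_names(covariates)]
  if (anyNA(beta)) abort("`params$beta` must cover all model terms.",
                         class = "hsuv_param_error")
  sd_slope <- params$sd_slope
  if (!is.null(sd_slope) && sd_slope < 1e-8) sd_slope <- NULL
  if (params$sd_intercept <= 0 || params$sd_resid <= 0) {
    abort("Variance-component SDs must be positive.",
          class = "hsuv_param_error")
  }
  r <- mf$u - as.numeric(mf$X %*% beta)
  pid <- mf$pid; tp <- mf$tpre
  sig2 <- params$sd_resid^2
  s11 <- as.numeric(rowsum(rep(1, mf$n), pid, reorder = TRUE))
  zr1 <- as.numeric(rowsum(r, pid, reorder = TRUE))
  rtr <- sum(r^2)
  tau0 <- params$sd_intercept
  if (is.null(sd_slope)) {
    g <- sig2 / tau0^2 + s11
    quad <- (rtr - sum(zr1^2 / g)) / sig2
    logdet <- sum((s11 - 1) * log(sig2)) + sum(log(g)) + mf$m * log(tau0^2)
  } else {
    tau1 <- sd_slope
    s12 <- as.numeric(rowsum(tp, pid, reorder = TRUE))
    s22 <- as.numeric(rowsum(tp^2, pid, reorder = TRUE))
    zr2 <- as.numeric(rowsum(r * tp, pid, reorder = TRUE))
    g11 <- sig2 / tau0^2 + s11
    g12 <- s12
    g22 <- sig2 / tau1^2 + s22
    det_g <- g11 * g22 - g12^2
    i11 <- g22 / det_g; i12 <- -g12 / det_g; i22 <- g11 / det_g
    quad <- (rtr - sum(i11 * zr1^2 + 2 * i12 * zr1 * zr2 + i22 * zr2^2)) / sig2
    logdet <- sum((s11 - 2) * log(sig2)) + sum(log(det_g)) +
      mf$m * (log(tau0^2) + log(tau1^2))
  }
  -0.5 * (mf$n * log(2 * pi) + logdet + quad)
}
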