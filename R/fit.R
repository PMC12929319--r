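#' Fit a longitudinal utility model
#'
#' Estimates one of four mixed-effects model families for EQ-5D-3L
#' health-state utility values by marginal maximum likelihood:
#'
#' * `"lmm"` — Gaussian linear mixed model on the raw utility scale
#'   (random intercept + optional random slope on the first-year time basis);
#'   the random effects are integrated analytically and the fixed effects
#'   profiled out by generalized least squares.
#' * `"beta"` — mixed beta regression of the compressed decrement
#'   `y* = compress((u_max - u)/(u_max - u_min))` with logit link and
#'   precision `phi`.
#' * `"twopart_beta"` — zero-inflated beta: a mixed logistic model for the
#'   ceiling state (utility exactly `u_max`, i.e. a raw decrement of 0) with
#'   its own random intercept, combined with a mixed beta regression of the
#'   positive decrements, compressed with `N` equal to the number of positive
#'   observations. The two parts share no parameters and are maximized
#'   separately; the reported likelihood is their sum.
#' * `"aldvmm"` — adjusted limited dependent variable mixture model: `K`
#'   normal components on the utility scale with censoring-induced masses at
#'   the boundaries (latent values above `psi1` observed as `u_max`, below
#'   `u_min` as `u_min`) and a shared patient random intercept. Fitted by
#'   multi-start quasi-Newton optimization; component labels are ordered by
#'   increasing intercept.
#'
#' Random effects without a closed form are integrated by adaptive
#' Gauss-Hermite quadrature centered per patient at the conditional mode
#' (`nodes` nodes per dimension, tensor grid in two dimensions).
#'
#' @param data Long-format questionnaire data: `patient_id`, `time` (years
#'   since transplantation), `hsuv`, and covariate columns. Rows with missing
#'   values on the model covariates are dropped and counted.
#' @param family Model family (see above).
#' @param covariates Covariate column names; default [default_covariates()].
#' @param re_slope Include a random slope on `t_pre` (ignored for `aldvmm`
#'   and the zero part, which use a random intercept only)?
#' @param nodes Gauss-Hermite nodes per random-effect dimension (>= 5).
#' @param K Number of ALDVMM latent classes. `K >= 3` is accepted but
#'   experimental (convergence is fragile at realistic sample sizes).
#' @param psi1 ALDVMM near-ceiling censoring threshold (utility units). If a
#'   `value_set` is supplied the default is its largest attainable value
#'   strictly below `u_max`.
#' @param value_set Optional [value_set()] used to default `psi1`.
#' @param multi_start Number of random starts for the ALDVMM.
#' @param seed Seed for the multi-start jitter.
#' @param u_min,u_max Utility bounds.
#' @param knot Time-basis changepoint (years).
#' @param center_age Center the age covariate at its sample mean? Off by
#'   default so the intercept refers to age 0 rather than the cohort mean.
#' @param compute_se Compute standard errors (numerical observed
#'   information)? Disable inside simulation loops for speed.
#' @return An object of class `hsuv_fit` with [tidy()], [glance()],
#'   [predict()][predict.hsuv_fit] and [autoplot()] methods.
#' @examples
#' coh <- simulate_cohort(n_patients = 120, seed = 7)
#' fit <- fit_hsuv(coh, family = "lmm", compute_se = FALSE)
#' glance(fit)
#' @export
fit_hsuv <- function(data, family = c("lmm", "beta", "twopart_beta", "aldvmm"),
                     covariates = default_covariates(),
                     re_slope = TRUE, nodes = 9, K = 1, psi1 = NULL,
                     value_set = NULL, multi_start = 10, seed = NULL,
                     u_min = -0.53, u_max = 1.00, knot = 1,
                     center_age = FALSE, compute_se = TRUE) {
  family <- match.arg(family)
  spec <- transform_spec(u_min, u_max)
  # the Gaussian family tolerates (unclamped synthetic) utilities outside
  # the attainable range; the bounded families do not
  mf <- build_model_frame(data, covariates, knot = knot, spec = spec,
                          center_age = center_age,
                          check_range = family != "lmm")
  if (K >= 3) {
    warn("K >= 3 latent classes is experimental; convergence is fragile.")
  }
  fitted <- switch(family,
    lmm = fit_family_lmm(mf, re_slope, compute_se),
    beta = fit_family_beta(mf, re_slope, nodes, compute_se),
    twopart_beta = fit_family_twopart(mf, re_slope, nodes, compute_se),
    aldvmm = fit_family_aldvmm(mf, K, psi1, value_set, nodes, multi_start,
                               seed, compute_se))
  if (fitted$convergence$code != 0 &&
      !isTRUE(fitted$convergence$acceptable)) {
    warn(paste0("Optimizer reported non-convergence (code ",
                fitted$convergence$code, "): ",
                fitted$convergence$message %||% ""))
  }
  structure(c(fitted, list(
    family = family, covariates = covariates, re_slope = re_slope,
    nodes = nodes, knot = knot, spec = spec, center_age = center_age,
    n_obs = mf$n, n_patients = mf$m,
    n_dropped_rows = mf$n_dropped_rows,
    n_dropped_patients = mf$n_dropped_patients,
    aic = -2 * fitted$loglik + 2 * fitted$n_par,
    bic = -2 * fitted$loglik + fitted$n_par * log(mf$n))),
    class = "hsuv_fit")
}

fit_family_lmm <- function(mf, re_slope, compute_se) {
  res <- fit_lmm_internal(mf, re_slope = re_slope, compute_se = compute_se)
  res$params <- list(family = "lmm", beta = res$beta,
                     sd_intercept = res$sd_intercept,
                     sd_slope = res$sd_slope, sd_resid = res$sd_resid)
  res
}

fit_family_beta <- function(mf, re_slope, nodes, compute_se,
                            y_override = NULL) {
  y <- y_override %||% rescale_to_decrement(mf$u, mf$spec)
  y_star <- compress_decrement(y, n_obs = mf$n)
  rule <- gh_rule(nodes)
  p <- ncol(mf$X)
  sc <- scale_design(mf$X)
  mfs <- mf; mfs$X <- sc$X
  start_lm <- lm.fit(mfs$X, qlogis(y_star))
  th0 <- c(start_lm$coefficients,
           log(3), log(0.8), if (re_slope) log(0.5))
  n_vc <- if (re_slope) 3L else 2L
  lower <- c(rep(-Inf, p), rep(log(1e-4), n_vc))
  upper <- c(rep(Inf, p), c(log(500), rep(log(10), n_vc - 1)))
  ob <- make_beta_objective(mfs, y_star, re_slope, rule)
  opt <- nlminb(th0, ob$fn, gradient = ob$gr,
                lower = lower, upper = upper,
                control = list(iter.max = 500, eval.max = 1500,
                               rel.tol = 1e-9))
  th <- opt$par
  beta <- setNames(unscale_beta(th[seq_len(p)], sc), colnames(mf$X))
  res <- list(
    beta = beta, phi = unname(exp(th[p + 1])),
    sd_intercept = unname(exp(th[p + 2])),
    sd_slope = if (re_slope) unname(exp(th[p + 3])) else NULL,
    loglik = -opt$objective, n_par = length(th),
    convergence = list(code = opt$convergence, message = opt$message,
                       iterations = opt$iterations,
                       acceptable = grepl("relative convergence|X-convergence|singular convergence",
                                          opt$message %||% "")))
  res$params <- list(family = "beta", beta = beta, phi = res$phi,
                     sd_intercept = res$sd_intercept, sd_slope = res$sd_slope)
  if (compute_se) {
    V <- cov_from_hessian(th, ob$fn)
    T_ <- unscale_transform(sc)
    Vb <- T_ %*% V[seq_len(p), seq_len(p), drop = FALSE] %*% t(T_)
    res$beta_se <- setNames(sqrt(pmax(diag(Vb), 0)), colnames(mf$X))
    se_vc <- sqrt(pmax(diag(V)[-seq_len(p)], 0))
    res$varcomp_se <- exp(th[-seq_len(p)]) * se_vc
    names(res$varcomp_se) <- c("phi", "sd_intercept",
                               if (re_slope) "sd_slope")
  }
  res
}

fit_zero_part <- function(mf, nodes, compute_se) {
  z <- as.integer(abs(mf$u - mf$spec$u_max) < 1e-8)
  rule <- gh_rule(nodes)
  p <- ncol(mf$X)
  sc <- scale_design(mf$X)
  mfs <- mf; mfs$X <- sc$X
  g0 <- suppressWarnings(
    stats::glm.fit(mfs$X, z, family = stats::binomial())$coefficients)
  th0 <- c(g0 * 1.2, log(1.5))   # inflate toward conditional-scale effects
  lower <- c(rep(-Inf, p), log(1e-4))
  upper <- c(rep(Inf, p), log(10))
  ob <- make_bernoulli_objective(mfs, z, rule)
  opt <- nlminb(th0, ob$fn, gradient = ob$gr,
                lower = lower, upper = upper,
                control = list(iter.max = 500, eval.max = 1500,
                               rel.tol = 1e-9))
  th <- opt$par
  res <- list(gamma = setNames(unscale_beta(th[seq_len(p)], sc),
                               colnames(mf$X)),
              sd_zero_intercept = unname(exp(th[p + 1])),
              loglik = -opt$objective, n_par = length(th),
              convergence = list(code = opt$convergence,
                                 message = opt$message,
                                 iterations = opt$iterations,
                                 acceptable = grepl("relative convergence|X-convergence|singular convergence",
                                                    opt$message %||% "")))
  if (compute_se) {
    V <- cov_from_hessian(th, ob$fn)
    T_ <- unscale_transform(sc)
    Vb <- T_ %*% V[seq_len(p), seq_len(p), drop = FALSE] %*% t(T_)
    res$gamma_se <- setNames(sqrt(pmax(diag(Vb), 0)), colnames(mf$X))
    res$sd_zero_se <- exp(th[p + 1]) * sqrt(max(diag(V)[p + 1], 0))
  }
  res
}

fit_family_twopart <- function(mf, re_slope, nodes, compute_se) {
  zero <- abs(mf$u - mf$spec$u_max) < 1e-8
  zp <- fit_zero_part(mf, nodes, compute_se)
  # conditional part: positive decrements only, compression N = their count
  keep <- !zero
  if (!any(keep)) {
    abort("All observations are at the ceiling; the conditional part is empty.",
          class = "hsuv_data_error")
  }
  sub <- mf
  sub$u <- mf$u[keep]; sub$X <- mf$X[keep, , drop = FALSE]
  sub$tpre <- mf$tpre[keep]; sub$tpost <- mf$tpost[keep]
  sub$pid <- match(mf$pid[keep], unique(mf$pid[keep]))
  sub$m <- max(sub$pid); sub$n <- sum(keep)
  cp <- fit_family_beta(sub, re_slope, nodes, compute_se)
  res <- list(
    gamma = zp$gamma, sd_zero_intercept = zp$sd_zero_intercept,
    beta = cp$beta, phi = cp$phi,
    sd_intercept = cp$sd_intercept, sd_slope = cp$sd_slope,
    loglik = zp$loglik + cp$loglik,
    n_par = zp$n_par + cp$n_par,
    loglik_parts = c(zero = zp$loglik, conditional = cp$loglik),
    convergence = list(
      code = max(zp$convergence$code, cp$convergence$code),
      message = paste("zero:", zp$convergence$message %||% "",
                      "| conditional:", cp$convergence$message %||% ""),
      iterations = zp$convergence$iterations + cp$convergence$iterations,
      acceptable = isTRUE(zp$convergence$acceptable) &&
        isTRUE(cp$convergence$acceptable)))
  res$params <- list(family = "twopart_beta", gamma = res$gamma,
                     sd_zero_intercept = res$sd_zero_intercept,
                     beta = res$beta, phi = res$phi,
                     sd_intercept = res$sd_intercept,
                     sd_slope = res$sd_slope)
  if (compute_se) {
    res$gamma_se <- zp$gamma_se
    res$beta_se <- cp$beta_se
    res$varcomp_se <- c(sd_zero_intercept = zp$sd_zero_se, cp$varcomp_se)
  }
  res
}

fit_family_aldvmm <- function(mf, K, psi1, value_set, nodes, multi_start,
                              seed, compute_se) {
  if (is.null(psi1)) {
    if (!is.null(value_set)) {
      grid <- enumerate_grid(value_set)
      psi1 <- max(grid[grid < mf$spec$u_max - 1e-9])
    } else {
      psi1 <- 0.9
    }
  }
  if (psi1 >= mf$spec$u_max) {
    abort("`psi1` must be strictly below `u_max`.",
          class = "hsuv_config_error")
  }
  rule <- gh_rule(nodes)
  p <- ncol(mf$X)
  u <- mf$u
  zero_eta <- numeric(mf$n)
  unpack <- function(th) {
    B <- matrix(th[seq_len(K * p)], K, p, byrow = TRUE,
                dimnames = list(NULL, colnames(mf$X)))
    sig <- exp(th[K * p + seq_len(K)])
    pi_c <- if (K > 1) {
      el <- c(0, th[K * p + K + seq_len(K - 1)])
      exp(el) / sum(exp(el))
    } else 1
    tau <- exp(th[length(th)])
    list(B = B, sig = sig, pi = pi_c, tau = tau)
  }
  cache <- new.env(parent = emptyenv())
  nll <- function(th) {
    pp <- unpack(th)
    eta <- mf$X %*% t(pp$B)            # n x K component means at b = 0
    ll_off <- function(b_off) {
      if (is.matrix(b_off)) {
        out <- matrix(NA_real_, nrow(b_off), ncol(b_off))
        for (j in seq_len(ncol(b_off))) {
          out[, j] <- aldvmm_obs_ll(u, eta + b_off[, j], pp$pi, pp$sig,
                                    psi1, mf$spec$u_min, mf$spec$u_max)
        }
        out
      } else {
        aldvmm_obs_ll(u, eta + b_off, pp$pi, pp$sig, psi1,
                      mf$spec$u_min, mf$spec$u_max)
      }
    }
    fam <- numeric_derivs(ll_off)
    v <- -sum(agh_loglik_1d(fam, zero_eta, mf$pid, mf$m, pp$tau, rule,
                            cache = cache))
    if (!is.finite(v)) 1e10 else v
  }
  # starts: LMM-based center with seeded jitter; rows of B concatenated
  base <- fit_lmm_internal(mf, re_slope = FALSE, compute_se = FALSE)
  make_start <- function(jit) {
    B0 <- matrix(rep(base$beta, each = K), K, p)
    B0[, 1] <- B0[, 1] + jit * seq(-0.2, 0.2, length.out = K) +
      rnorm(K, 0, 0.03 * jit)
    c(as.numeric(t(B0)),
      log(pmax(base$sd_resid * exp(rnorm(K, 0, 0.3 * jit)), 0.02)),
      if (K > 1) rnorm(K - 1, 0, 0.5 * jit),
      log(max(base$sd_intercept, 0.02)))
  }
  if (!is.null(seed)) set.seed(seed)
  n_starts <- if (K == 1) 1L else as.integer(multi_start)
  best <- NULL
  lower <- c(rep(-Inf, K * p), rep(log(1e-3), K), rep(-8, max(K - 1, 0)),
             log(1e-4))
  upper <- c(rep(Inf, K * p), rep(log(2), K), rep(8, max(K - 1, 0)), log(5))
  for (s in seq_len(n_starts)) {
    th0 <- make_start(jit = if (s == 1) 1 else 1 + 0.5 * s)
    opt <- tryCatch(
      nlminb(th0, nll, lower = lower, upper = upper,
             control = list(iter.max = 400, eval.max = 1200)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$objective < best$objective)) {
      best <- opt
    }
  }
  if (is.null(best)) {
    abort("ALDVMM failed to converge from any start.",
          class = "hsuv_convergence_error")
  }
  pp <- unpack(best$par)
  ord <- order(pp$B[, 1])              # label switching: sort by intercept
  pp$B <- pp$B[ord, , drop = FALSE]
  pp$sig <- pp$sig[ord]
  pp$pi <- if (K > 1) pp$pi[ord] else 1
  res <- list(
    beta = pp$B, sigma = pp$sig, pi = pp$pi, sd_intercept = pp$tau,
    psi1 = psi1, K = K,
    loglik = -best$objective, n_par = length(best$par),
    convergence = list(code = best$convergence, message = best$message,
                       iterations = best$iterations,
                       acceptable = grepl("relative convergence|X-convergence|singular convergence",
                                          best$message %||% "")))
  res$params <- list(family = "aldvmm", beta = pp$B, pi = pp$pi,
                     sigma = pp$sig, sd_intercept = pp$tau, psi1 = psi1)
  if (compute_se) {
    se <- se_from_hessian(best$par, nll)
    res$beta_se <- matrix(se[seq_len(K * p)], K, p, byrow = TRUE,
                          dimnames = list(NULL, colnames(mf$X)))[ord, ,
                                                                 drop = FALSE]
  }
  res
}

# Internal standardization of the design matrix for quasi-Newton
# optimization: non-intercept columns are centered and scaled to unit SD,
# which conditions the Hessian; estimates are mapped back exactly afterward.
scale_design <- function(X) {
  ctr <- colMeans(X); ctr[1] <- 0
  scl <- apply(X, 2, sd); scl[1] <- 1
  scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Xs[, 1] <- 1
  list(X = Xs, center = ctr, scale = scl)
}

# linear map from scaled-space coefficients to original-space ones
unscale_transform <- function(sc) {
  p <- length(sc$scale)
  T_ <- diag(1 / sc$scale)
  T_[1, ] <- -sc$center / sc$scale
  T_[1, 1] <- 1
  T_
}

unscale_beta <- function(beta_s, sc) {
  as.numeric(unscale_transform(sc) %*% beta_s)
}

se_from_hessian <- function(th, nll) {
  V <- cov_from_hessian(th, nll)
  d <- diag(V)
  ifelse(d > 0, sqrt(d), NA_real_)
}

cov_from_hessian <- function(th, nll) {
  H <- tryCatch(optimHess(th, nll), error = function(e) NULL)
  if (is.null(H)) return(matrix(NA_real_, length(th), length(th)))
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(matrix(NA_real_, length(th), length(th)))
  V
}
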