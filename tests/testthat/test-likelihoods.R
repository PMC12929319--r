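# Likelihood oracles: the quadrature path is checked against the analytic
# Gaussian marginal form and against brute-force dense-covariance and
# one-dimensional numerical integration, all on small seed-fixed cohorts.

# independent oracle: per-patient dense multivariate-normal likelihood
dense_lmm_loglik <- function(coh, params, covariates) {
  tb <- time_basis(coh$time)
  X <- cbind(1, as.matrix(coh[covariates]), tb$t_pre, tb$t_post)
  beta <- params$beta
  r <- coh$hsuv - as.numeric(X %*% beta)
  ll <- 0
  for (id in unique(coh$patient_id)) {
    idx <- which(coh$patient_id == id)
    Z <- cbind(1, tb$t_pre[idx])
    D <- diag(c(params$sd_intercept^2, (params$sd_slope %||% 0)^2))
    S <- Z %*% D %*% t(Z) + diag(params$sd_resid^2, length(idx))
    ll <- ll - 0.5 * (length(idx) * log(2 * pi) +
                        determinant(S)$modulus[1] +
                        sum(r[idx] * solve(S, r[idx])))
  }
  ll
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("closed-form linear-mixed likelihood matches a dense-matrix oracle", {
  coh <- small_cohort(n = 20, seed = 1)
  p <- attr(coh, "truth")
  covs <- default_covariates()
  expect_equal(loglik_lmm_closed_form(coh, p, covs),
               dense_lmm_loglik(coh, p, covs), tolerance = 1e-10)
})

test_that("quadrature and closed-form Gaussian likelihoods agree to 1e-6", {
  coh <- small_cohort(n = 20, seed = 1)
  p <- attr(coh, "truth")
  cf <- loglik_lmm_closed_form(coh, p)
  for (nodes in c(9, 15)) {
    q <- loglik_marginal_quadrature(coh, p, nodes = nodes)
    expect_equal(q, cf, tolerance = 1e-6)
  }
})

test_that("quadrature beta likelihood matches adaptive 1-D integration", {
  pp <- default_beta_params(); pp$sd_slope <- NULL
  coh <- small_cohort(n = 12, seed = 3, family = "beta", params = pp)
  q <- loglik_marginal_quadrature(coh, pp, nodes = 15)
  # brute force: integrate each patient's conditional likelihood over b0
  tb <- time_basis(coh$time)
  X <- cbind(1, as.matrix(coh[default_covariates()]), tb$t_pre, tb$t_post)
  eta <- as.numeric(X %*% pp$beta)
  y_star <- compress_decrement(rescale_to_decrement(coh$hsuv),
                               n_obs = nrow(coh))
  ll <- 0
  for (id in unique(coh$patient_id)) {
    idx <- which(coh$patient_id == id)
    f <- function(b) vapply(b, function(bb) {
      mu <- plogis(eta[idx] + bb)
      exp(sum(dbeta(y_star[idx], mu * pp$phi, (1 - mu) * pp$phi,
                    log = TRUE))) *
        dnorm(bb, 0, pp$sd_intercept)
    }, numeric(1))
    ll <- ll + log(integrate(f, -8, 8, rel.tol = 1e-12)$value)
  }
  expect_equal(q, ll, tolerance = 1e-6)
})

test_that("vanishing random-effect variance collapses to the b = 0 likelihood", {
  pp <- default_beta_params()
  pp$sd_intercept <- 1e-9; pp$sd_slope <- 1e-9
  coh <- small_cohort(n = 15, seed = 4, family = "beta",
                      params = default_beta_params())
  q <- loglik_marginal_quadrature(coh, pp, family = "beta")
  y_star <- compress_decrement(rescale_to_decrement(coh$hsuv),
                               n_obs = nrow(coh))
  tb <- time_basis(coh$time)
  X <- cbind(1, as.matrix(coh[default_covariates()]), tb$t_pre, tb$t_post)
  mu <- plogis(as.numeric(X %*% pp$beta))
  expect_equal(q, sum(dbeta(y_star, mu * pp$phi, (1 - mu) * pp$phi,
                            log = TRUE)), tolerance = 1e-6)
})

test_that("per-observation conditional densities hit their closed-form cases", {
  spec <- transform_spec(n_obs = 100)
  # beta with mu 0.5, phi 2 is the uniform density: log-density 0 anywhere
  u_mid <- back_transform(decompress_decrement(0.37, 100), spec)
  expect_equal(obs_loglik_conditional(u_mid, qlogis(0.5), "beta",
                                      list(phi = 2), spec = spec),
               0, tolerance = 1e-10)
  # degenerate zero-inflation: ceiling certain
  expect_equal(obs_loglik_conditional(1, eta = 0, family = "twopart_beta",
                                      params = list(phi = 5),
                                      eta_zero = 50, spec = spec),
               0, tolerance = 1e-10)
  # single-class mixture with mean at the censoring threshold: mass 1/2 at ceiling
  expect_equal(obs_loglik_conditional(1, eta = 0.9, family = "aldvmm",
                                      params = list(pi = 1, sigma = 0.1,
                                                    psi1 = 0.9),
                                      spec = spec),
               log(0.5), tolerance = 1e-10)
  # normal family is the plain density
  expect_equal(obs_loglik_conditional(0.8, 0.85, "lmm",
                                      list(sd_resid = 0.12), spec = spec),
               dnorm(0.8, 0.85, 0.12, log = TRUE))
})

test_that("Gaussian scaling identity holds at the data mean", {
  spec <- transform_spec()
  u <- rep(0.8, 7)
  l1 <- sum(obs_loglik_conditional(u, 0.8, "lmm", list(sd_resid = 0.1),
                                   spec = spec))
  l2 <- sum(obs_loglik_conditional(u, 0.8, "lmm", list(sd_resid = 0.2),
                                   spec = spec))
  expect_equal(l1 - l2, 7 * log(2), tolerance = 1e-12)
})

test_that("node refinement changes the beta marginal by little", {
  coh <- small_cohort(n = 25, seed = 5, family = "beta")
  p <- attr(coh, "truth")
  l9 <- loglik_marginal_quadrature(coh, p, nodes = 9)
  l15 <- loglik_marginal_quadrature(coh, p, nodes = 15)
  l21 <- loglik_marginal_quadrature(coh, p, nodes = 21)
  expect_lt(abs(l15 - l21), 1e-4)
  expect_lt(abs(l9 - l21), 1e-2)
})

test_that("parameter-domain errors are raised, not silently absorbed", {
  spec <- transform_spec(n_obs = 10)
  expect_error(obs_loglik_conditional(0.5, 0, "beta", list(phi = -1),
                                      spec = spec),
               class = "hsuv_param_error")
  expect_error(obs_loglik_conditional(2, 0, "lmm", list(sd_resid = 0.1),
                                      spec = spec),
               class = "hsuv_data_error")
  expect_error(loglik_marginal_quadrature(small_cohort(5, 1),
                                          default_lmm_params(), nodes = 3),
               class = "hsuv_config_error")
})
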