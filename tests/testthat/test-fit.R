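test_that("the linear mixed fit matches lme4 on seed-fixed data", {
  skip_if_not_installed("lme4")
  coh <- small_cohort(n = 400, seed = 21)
  fit <- fit_hsuv(coh, family = "lmm", compute_se = TRUE)
  coh$tp <- pmin(coh$time, 1); coh$tq <- pmax(coh$time - 1, 0)
  lf <- lme4::lmer(
    hsuv ~ age + male + bmi_gt30 + diabetes + cardiovascular +
      dialysis_years + tp + tq + (1 | patient_id) +
      (0 + tp | patient_id),
    data = coh, REML = FALSE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-4)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$sd_intercept,
               vc$sdcor[vc$grp == "patient_id" & vc$var1 == "(Intercept)"],
               tolerance = 1e-3)
  expect_equal(fit$sd_resid, vc$sdcor[vc$grp == "Residual"],
               tolerance = 1e-3)
})

test_that("the mixed beta fit agrees with glmmTMB up to integration method", {
  skip_if_not_installed("glmmTMB")
  pp <- default_beta_params(); pp$sd_slope <- NULL
  coh <- small_cohort(n = 300, seed = 22, family = "beta", params = pp)
  fit <- suppressWarnings(
    fit_hsuv(coh, family = "beta", re_slope = FALSE, compute_se = FALSE))
  coh$ys <- compress_decrement(rescale_to_decrement(coh$hsuv),
                               n_obs = nrow(coh))
  coh$tp <- pmin(coh$time, 1); coh$tq <- pmax(coh$time - 1, 0)
  tm <- glmmTMB::glmmTMB(
    ys ~ age + male + bmi_gt30 + diabetes + cardiovascular +
      dialysis_years + tp + tq + (1 | patient_id),
    data = coh, family = glmmTMB::beta_family())
  # glmmTMB integrates by Laplace; agreement is looser than an exact oracle
  expect_equal(unname(fit$beta), unname(glmmTMB::fixef(tm)$cond),
               tolerance = 0.02)
  expect_equal(unname(fit$phi), unname(glmmTMB::sigma(tm)),
               tolerance = 0.05)
})

test_that("ALDVMM with one class and inactive censoring reproduces the LMM", {
  pp <- default_lmm_params(); pp$sd_slope <- 0
  coh <- small_cohort(n = 250, seed = 4, family = "lmm", params = pp)
  u_lo <- min(coh$hsuv) - 0.02; u_hi <- max(coh$hsuv) + 0.02
  lmm <- fit_hsuv(coh, family = "lmm", re_slope = FALSE, compute_se = FALSE)
  ald <- suppressWarnings(
    fit_hsuv(coh, family = "aldvmm", K = 1, psi1 = u_hi - 0.01,
             u_min = u_lo, u_max = u_hi, compute_se = FALSE))
  expect_equal(unname(ald$beta[1, ]), unname(lmm$beta), tolerance = 1e-3)
  expect_equal(ald$sigma, lmm$sd_resid, tolerance = 1e-3)
  expect_equal(ald$sd_intercept, lmm$sd_intercept, tolerance = 1e-3)
  expect_equal(ald$loglik, lmm$loglik, tolerance = 1e-4)
})

test_that("a zero-free two-part fit reproduces the one-part beta fit", {
  pp <- default_beta_params()
  coh <- small_cohort(n = 200, seed = 23, family = "beta", params = pp)
  coh <- coh[coh$hsuv < 1, ]   # drop boundary-clamped draws so no ceilings
  one <- suppressWarnings(fit_hsuv(coh, family = "beta",
                                   compute_se = FALSE))
  two <- suppressWarnings(fit_hsuv(coh, family = "twopart_beta",
                                   compute_se = FALSE))
  expect_equal(unname(two$beta), unname(one$beta), tolerance = 1e-4)
  expect_equal(two$phi, one$phi, tolerance = 1e-4)
  expect_equal(two$sd_intercept, one$sd_intercept, tolerance = 1e-3)
})

test_that("two-class mixtures are recovered with ordered labels", {
  pp <- default_aldvmm_params()
  cn <- colnames(pp$beta)
  pp$beta <- rbind(c(0.45, rep(0, 8)), c(0.92, rep(0, 8)))
  colnames(pp$beta) <- cn
  pp$pi <- c(0.35, 0.65); pp$sigma <- c(0.10, 0.06)
  pp$sd_intercept <- 0.08; pp$psi1 <- 0.9
  coh <- simulate_cohort(400, seed = 2,
                         cfg = cohort_config(family = "aldvmm", params = pp))
  fit <- suppressWarnings(
    fit_hsuv(coh, family = "aldvmm", covariates = character(0), K = 2,
             psi1 = 0.9, multi_start = 4, seed = 1, compute_se = FALSE))
  expect_true(fit$beta[1, 1] <= fit$beta[2, 1])   # label ordering
  expect_lt(max(abs(fit$beta[, 1] - c(0.45, 0.92))), 0.1)
  expect_lt(max(abs(fit$pi - c(0.35, 0.65))), 0.1)
  expect_equal(sum(fit$pi), 1, tolerance = 1e-9)
})

test_that("information criteria follow their definitions", {
  coh <- small_cohort(n = 100, seed = 24)
  fit <- fit_hsuv(coh, family = "lmm", compute_se = FALSE)
  ic <- information_criteria(fit)
  expect_equal(ic$AIC, -2 * fit$loglik + 2 * fit$n_par)
  expect_equal(ic$BIC, -2 * fit$loglik + fit$n_par * log(fit$n_obs))
  # nested model: BIC difference identity
  fit0 <- fit_hsuv(coh, family = "lmm",
                   covariates = setdiff(default_covariates(), "diabetes"),
                   compute_se = FALSE)
  expect_equal(fit$bic - fit0$bic,
               -2 * (fit$loglik - fit0$loglik) + log(fit$n_obs),
               tolerance = 1e-8)
})

test_that("coefficient recovery at modest scale is within sampling error", {
  coh <- small_cohort(n = 900, seed = 25)
  fit <- fit_hsuv(coh, family = "lmm", compute_se = TRUE)
  truth <- default_lmm_params()
  td <- tidy(fit)
  est <- td[td$component == "mean", ]
  for (nm in c("diabetes", "male", "t_post")) {
    row <- est[est$term == nm, ]
    expect_lt(abs(row$estimate - truth$beta[[nm]]) / row$std.error, 4)
  }
})

test_that("tidy and glance expose the documented columns", {
  coh <- small_cohort(n = 80, seed = 26, family = "twopart_beta")
  fit <- suppressWarnings(fit_hsuv(coh, family = "twopart_beta",
                                   compute_se = FALSE))
  td <- tidy(fit)
  expect_named(td, c("component", "term", "estimate", "std.error",
                     "conf.low", "conf.high"))
  expect_setequal(unique(td$component), c("zero", "conditional"))
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$n_obs)
  expect_true(is.finite(gl$BIC))
})
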