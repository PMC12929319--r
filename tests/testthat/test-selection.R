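test_that("empty candidate lists pass through the two-stage procedure", {
  coh <- small_cohort(n = 60, seed = 31)
  scr <- univariate_screen(coh, "lmm", candidates = character(0))
  expect_equal(nrow(scr), 0)
  fw <- forward_select(coh, "lmm", screened = character(0))
  expect_equal(fw$selected, character(0))
})

test_that("screen statistics are valid likelihood-ratio quantities", {
  coh <- small_cohort(n = 250, seed = 32)
  scr <- univariate_screen(coh, "lmm",
                           candidates = c("diabetes", "neoplasia",
                                          "donor_age"))
  expect_true(all(scr$lrt >= 0))
  expect_true(all(scr$p_value >= 0 & scr$p_value <= 1))
  expect_true(all(scr$df == 1))
  # the procedure ignores row order
  perm <- coh[sample(nrow(coh)), ]
  scr2 <- univariate_screen(perm, "lmm",
                            candidates = c("diabetes", "neoplasia",
                                           "donor_age"))
  expect_equal(scr$p_value, scr2$p_value, tolerance = 1e-6)
})

test_that("forward selection adds true effects and its path is monotone", {
  coh <- small_cohort(n = 900, seed = 33)
  sel <- select_covariates(coh, "lmm",
                           candidates = c("diabetes", "male",
                                          "neoplasia", "donor_age"))
  expect_true(all(c("diabetes", "male") %in% sel$selected))
  # log-likelihood along accepted steps never decreases
  accepted <- sel$steps[sel$steps$p_value < 0.05, ]
  if (nrow(accepted) > 1) {
    expect_true(all(diff(tapply(accepted$loglik, accepted$step, max)) > -1e-8))
  }
})

test_that("a duplicated candidate cannot enter twice", {
  coh <- small_cohort(n = 500, seed = 34)
  coh$diabetes_copy <- coh$diabetes
  # the duplicated column makes the design singular; the fitter warns
  fw <- suppressWarnings(
    forward_select(coh, "lmm", screened = c("diabetes", "diabetes_copy")))
  expect_lte(sum(c("diabetes", "diabetes_copy") %in% fw$selected), 1)
})

test_that("class-count choice by BIC handles the trivial and real cases", {
  pp <- default_lmm_params(); pp$sd_slope <- 0
  coh <- small_cohort(n = 150, seed = 35, family = "lmm", params = pp)
  u_hi <- max(coh$hsuv) + 0.02
  one <- select_aldvmm_classes(coh, covariates = character(0), K_values = 1,
                               psi1 = u_hi - 0.01, u_min = min(coh$hsuv) - 0.02,
                               u_max = u_hi)
  expect_equal(one$K, 1)
  # well-separated two-class data prefer K = 2
  pp2 <- default_aldvmm_params()
  cn <- colnames(pp2$beta)
  pp2$beta <- rbind(c(0.45, rep(0, 8)), c(0.92, rep(0, 8)))
  colnames(pp2$beta) <- cn
  pp2$pi <- c(0.35, 0.65); pp2$sigma <- c(0.10, 0.06)
  pp2$sd_intercept <- 0.08; pp2$psi1 <- 0.9
  coh2 <- simulate_cohort(250, seed = 36,
                          cfg = cohort_config(family = "aldvmm",
                                              params = pp2))
  sel2 <- suppressWarnings(
    select_aldvmm_classes(coh2, covariates = character(0),
                          K_values = c(1, 2), multi_start = 3, seed = 1))
  expect_equal(sel2$K, 2)
  expect_equal(nrow(sel2$table), 2)
})
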