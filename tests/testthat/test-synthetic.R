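test_that("identical config and seed give identical cohorts", {
  a <- simulate_cohort(n_patients = 60, seed = 7)
  b <- simulate_cohort(n_patients = 60, seed = 7)
  expect_identical(a, b)
  c_ <- simulate_cohort(n_patients = 60, seed = 8)
  expect_false(identical(a$hsuv, c_$hsuv))
})

test_that("degenerate covariate settings are honoured exactly", {
  cfg <- cohort_config(n_patients = 50, male_prob = 1)
  pats <- generate_covariates(cfg, seed = 1)
  expect_true(all(pats$male == 1))
  expect_true(all(pats$age >= 18 & pats$age <= 90))
  expect_true(all(pats$bmi_lt18 + pats$bmi_gt30 <= 1))
})

test_that("visit counts and times follow the configured process", {
  cfg <- cohort_config(n_patients = 40, visit_count_probs = c(1, 0))
  pats <- generate_covariates(cfg, seed = 2)
  vis <- generate_visits(cfg, pats, seed = 2)
  expect_equal(nrow(vis), 40)
  cfg2 <- cohort_config(n_patients = 300)
  vis2 <- generate_visits(cfg2, generate_covariates(cfg2, seed = 3), seed = 3)
  expect_true(all(vis2$time >= 0.08 & vis2$time <= 29.5))
  expect_true(all(vis2$patient_id == sort(vis2$patient_id)))
  # sorted within patient
  expect_true(all(unlist(tapply(vis2$time, vis2$patient_id,
                                function(t) !is.unsorted(t)))))
})

test_that("noise-free linear generation returns the intercept everywhere", {
  pp <- default_lmm_params()
  pp$beta[] <- 0; pp$beta["(Intercept)"] <- 0.881
  pp$sd_intercept <- 1e-12; pp$sd_slope <- 1e-12; pp$sd_resid <- 1e-12
  coh <- simulate_cohort(n_patients = 25, seed = 5,
                         cfg = cohort_config(family = "lmm", params = pp))
  expect_equal(coh$hsuv, rep(0.881, nrow(coh)), tolerance = 1e-9)
})

test_that("two-part generation emits exact ceiling utilities", {
  coh <- small_cohort(n = 400, seed = 6, family = "twopart_beta")
  share <- mean(coh$hsuv == 1)
  expect_gt(share, 0.2)
  expect_lt(share, 0.6)
  expect_true(all(coh$hsuv <= 1 & coh$hsuv >= -0.53))
})

test_that("empirical covariate moments approach configured values with n", {
  cfg <- cohort_config(n_patients = 4000)
  pats <- generate_covariates(cfg, seed = 11)
  expect_lt(abs(mean(pats$male) - 0.630), 0.03)
  expect_lt(abs(mean(pats$diabetes) - 0.136), 0.02)
  expect_lt(abs(mean(pats$dialysis_years) - 2.5), 0.2)
  expect_lt(abs(sd(pats$dialysis_years) - 3.3), 0.3)
  expect_lt(abs(mean(pats$donor_age) - 51.6), 0.7)
})

test_that("invalid configurations are rejected up front", {
  expect_error(cohort_config(male_prob = 1.3), class = "hsuv_config_error")
  expect_error(cohort_config(bmi_probs = c(0.5, 0.2, 0.1)),
               class = "hsuv_config_error")
  expect_error(cohort_config(visit_count_probs = c(0.8, 0.4)),
               class = "hsuv_config_error")
})

test_that("an empty cohort round-trips through the CSV contract", {
  coh <- simulate_cohort(n_patients = 0, seed = 1)
  expect_equal(nrow(coh), 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  expect_true(file.exists(f))
})

test_that("discretization snaps interior utilities onto the tariff grid", {
  vs <- french_like_value_set()
  cfg <- cohort_config(n_patients = 150, family = "twopart_beta",
                       discretize = TRUE, value_set = vs)
  coh <- simulate_cohort(seed = 9, cfg = cfg)
  grid <- enumerate_grid(vs)
  interior <- coh$hsuv[coh$hsuv < 1 & coh$hsuv > -0.53]
  expect_true(all(vapply(interior,
                         function(u) min(abs(grid - u)) < 1e-9, logical(1))))
})

test_that("covariate missingness is generated and counted on fitting", {
  cfg <- cohort_config(n_patients = 150, missing_rate = 0.02)
  coh <- simulate_cohort(seed = 12, cfg = cfg)
  expect_gt(sum(is.na(coh)), 0)
  fit <- suppressMessages(fit_hsuv(coh, family = "lmm", compute_se = FALSE))
  expect_gt(fit$n_dropped_rows, 0)
  expect_equal(fit$n_obs + fit$n_dropped_rows, nrow(coh))
})
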