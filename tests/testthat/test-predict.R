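# Prediction engine: reference-profile arithmetic, boundedness, continuity
# at the knot, trajectories and QALY integration, JSON round-trips.

# an lmm fit object assembled from known coefficients (no refitting)
manual_lmm_fit <- function(params = default_lmm_params()) {
  structure(list(
    family = "lmm", covariates = default_covariates(), re_slope = TRUE,
    nodes = 9, knot = 1, spec = transform_spec(), center_age = FALSE,
    beta = params$beta, sd_intercept = params$sd_intercept,
    sd_slope = params$sd_slope, sd_resid = params$sd_resid,
    loglik = NA_real_, n_par = 12, aic = NA_real_, bic = NA_real_,
    n_obs = 5679L, n_patients = 2787L,
    n_dropped_rows = 0L, n_dropped_patients = 0L,
    convergence = list(code = 0L)), class = "hsuv_fit")
}

test_that("reference-profile predictions match coefficient arithmetic", {
  fit <- manual_lmm_fit()
  woman <- dplyr::mutate(reference_profile(male = 0), time = 0)
  man <- dplyr::mutate(reference_profile(male = 1), time = 0)
  expect_equal(predict(fit, woman), 0.881 - 0.002 * 50, tolerance = 1e-12)
  expect_equal(predict(fit, man), 0.881 - 0.002 * 50 + 0.074,
               tolerance = 1e-12)
})

test_that("a manual two-part prediction reproduces hand arithmetic", {
  # P0 = 0.5 and conditional mean decrement 0.4 give decrement 0.2,
  # i.e. utility 1 - 0.2 * 1.53 = 0.694
  beta <- c(`(Intercept)` = qlogis(0.4), age = 0, male = 0, bmi_gt30 = 0,
            diabetes = 0, cardiovascular = 0, dialysis_years = 0,
            t_pre = 0, t_post = 0)
  gamma <- beta; gamma[["(Intercept)"]] <- 0   # plogis(0) = 0.5
  fit <- structure(list(
    family = "twopart_beta", covariates = default_covariates(),
    re_slope = TRUE, nodes = 9, knot = 1, spec = transform_spec(),
    center_age = FALSE, beta = beta, gamma = gamma, phi = 5,
    sd_intercept = 0.7, sd_slope = 0.8, sd_zero_intercept = 2,
    loglik = NA_real_, n_par = 23, n_obs = 100L, n_patients = 50L,
    n_dropped_rows = 0L, n_dropped_patients = 0L,
    convergence = list(code = 0L)), class = "hsuv_fit")
  pred <- predict(fit, dplyr::mutate(reference_profile(), time = 0))
  expect_equal(pred, 1 - 0.2 * 1.53, tolerance = 1e-12)
})

test_that("predictions are continuous at the knot for every family", {
  newd <- dplyr::bind_rows(
    dplyr::mutate(reference_profile(), time = 1 - 1e-9),
    dplyr::mutate(reference_profile(), time = 1 + 1e-9))
  for (family in c("lmm", "beta", "twopart_beta", "aldvmm")) {
    coh <- small_cohort(n = 60, seed = 51, family = family)
    fit <- suppressWarnings(fit_hsuv(coh, family = family,
                                     multi_start = 2, seed = 1,
                                     compute_se = FALSE))
    p <- predict(fit, newd)
    expect_lt(abs(p[1] - p[2]), 1e-6)
  }
})

test_that("all families predict inside the attainable utility range", {
  set.seed(52)
  grid <- tidyr::crossing(
    age = c(18, 50, 88), male = 0:1, diabetes = 0:1,
    bmi_gt30 = 0:1, cardiovascular = 0:1, dialysis_years = c(0, 12),
    time = c(0, 0.5, 3, 25))
  for (family in c("lmm", "beta", "twopart_beta", "aldvmm")) {
    coh <- small_cohort(n = 60, seed = 53, family = family)
    fit <- suppressWarnings(fit_hsuv(coh, family = family,
                                     multi_start = 2, seed = 1,
                                     compute_se = FALSE))
    for (mode in c("conditional_b0", "marginal")) {
      p <- predict(fit, grid, mode = mode)
      expect_true(all(p >= -0.53 - 1e-12 & p <= 1 + 1e-12))
    }
  }
})

test_that("marginal and conditional means differ for nonlinear families", {
  coh <- small_cohort(n = 150, seed = 54, family = "twopart_beta")
  fit <- suppressWarnings(fit_hsuv(coh, family = "twopart_beta",
                                   compute_se = FALSE))
  newd <- dplyr::mutate(reference_profile(), time = 2)
  pc <- predict(fit, newd, mode = "conditional_b0")
  pm <- predict(fit, newd, mode = "marginal")
  expect_false(isTRUE(all.equal(pc, pm, tolerance = 1e-6)))
})

test_that("trajectories integrate to the expected QALYs", {
  fit <- manual_lmm_fit()
  # zero out the slopes: a flat trajectory integrates to u * years
  fit$beta[c("t_pre", "t_post")] <- 0
  tr <- predict_trajectory(fit, reference_profile(), times = c(0, 1))
  expect_equal(tr$hsuv_pred[1], tr$hsuv_pred[2])
  q <- qaly(tr)
  expect_equal(q$qaly, tr$hsuv_pred[1], tolerance = 1e-12)
  # piecewise-linear trajectory: trapezoid equals exact integral
  fit2 <- manual_lmm_fit()
  tr2 <- predict_trajectory(fit2, reference_profile(),
                            times = seq(0, 3, by = 0.5))
  q2 <- qaly(tr2)
  u0 <- predict(fit2, dplyr::mutate(reference_profile(), time = 0))
  u1 <- predict(fit2, dplyr::mutate(reference_profile(), time = 1))
  u3 <- predict(fit2, dplyr::mutate(reference_profile(), time = 3))
  exact <- (u0 + u1) / 2 + (u1 + u3) / 2 * 2
  expect_equal(q2$qaly, exact, tolerance = 1e-10)
  expect_s3_class(autoplot(tr2), "ggplot")
})

test_that("fitted models survive a JSON round-trip with identical predictions", {
  newd <- tidyr::crossing(reference_profile(), time = c(0, 0.7, 4))
  for (family in c("lmm", "twopart_beta", "aldvmm")) {
    coh <- small_cohort(n = 60, seed = 55, family = family)
    fit <- suppressWarnings(fit_hsuv(coh, family = family,
                                     multi_start = 2, seed = 1,
                                     compute_se = FALSE))
    f <- withr::local_tempfile(fileext = ".json")
    write_hsuv_model(fit, f)
    re <- read_hsuv_model(f)
    expect_equal(predict(re, newd), predict(fit, newd), tolerance = 1e-12)
    expect_equal(glance(re)$BIC, glance(fit)$BIC, tolerance = 1e-9)
  }
})

test_that("cohort CSVs round-trip and score profiles on read", {
  coh <- small_cohort(n = 20, seed = 56)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$hsuv, coh$hsuv, tolerance = 1e-12)
  # profile-format input is scored with the supplied value set
  f2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(patient_id = 1:2, time = c(0.5, 1),
                                  profile = c("11111", "21131")), f2)
  scored <- read_cohort(f2, value_set = toy_value_set())
  expect_equal(scored$hsuv, c(1, 0.55))
  expect_error(read_cohort(f2), class = "hsuv_data_error")
})

test_that("prediction rejects malformed inputs", {
  fit <- manual_lmm_fit()
  expect_error(predict(fit, tibble::tibble(age = 50, time = 1)),
               class = "hsuv_data_error")
  expect_error(predict(fit, dplyr::mutate(reference_profile(), time = -1)),
               class = "hsuv_range_error")
})
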