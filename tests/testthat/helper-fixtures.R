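# Shared fixtures: all synthetic, built in code.

toy_value_set <- function() {
  value_set(
    full_health = 1,
    decrements = rbind(level2 = c(0.1, 0, 0, 0, 0),
                       level3 = c(0.3, 0, 0, 0.3, 0)),
    any_problem = 0.05
  )
}

# a value set whose worst profile reaches exactly -0.53
french_like_value_set <- function() {
  value_set(
    full_health = 1,
    decrements = rbind(level2 = c(0.05, 0.05, 0.05, 0.05, 0.05),
                       level3 = c(0.25, 0.25, 0.25, 0.25, 0.25)),
    any_problem = 0.10, any_level3 = 0.18
  )
}

random_value_set <- function() {
  dec2 <- runif(5, 0, 0.15)
  dec3 <- dec2 + runif(5, 0, 0.15)   # level 3 at least as bad as level 2
  value_set(full_health = 1,
            decrements = rbind(dec2, dec3),
            any_problem = runif(1, 0, 0.1),
            any_level3 = runif(1, 0, 0.1))
}

small_cohort <- function(n = 80, seed = 42, family = "lmm", ...) {
  simulate_cohort(n_patients = n, seed = seed,
                  cfg = cohort_config(family = family, ...))
}

# reference covariate rows for prediction tests
reference_profile <- function(male = 1, age = 50) {
  tibble::tibble(age = age, male = male, bmi_gt30 = 0, diabetes = 0,
                 cardiovascular = 0, dialysis_years = 0)
}
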