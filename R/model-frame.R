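# Internal model frame: validated long-format cohort rows arranged for the
# likelihood code. One row per questionnaire; patients indexed 1..m in order
# of first appearance.

#' Default covariate set of the final utility models
#'
#' Recipient age (years), male sex, BMI above 30 kg/m2, history of diabetes,
#' history of cardiovascular disease, and years on dialysis before
#' transplantation: the baseline characteristics retained by
#' likelihood-ratio selection in the cohort analysis the package emulates.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("age", "male", "bmi_gt30", "diabetes", "cardiovascular", "dialysis_years")
}

#' All candidate baseline covariates
#'
#' The full candidate set considered for selection: [default_covariates()]
#' plus BMI under 18, history of neoplasia, hypertension, first (versus
#' second) transplantation, relapsing initial nephropathy and donor age.
#'
#' @return Character vector of column names.
#' @export
candidate_covariates <- function() {
  c(default_covariates(),
    "bmi_lt18", "neoplasia", "hypertension", "first_transplant",
    "relapsing_nephropathy", "donor_age")
}

build_model_frame <- function(data, covariates, knot = 1,
                              spec = transform_spec(),
                              outcome = "hsuv", id = "patient_id",
                              time = "time", center_age = FALSE,
                              check_range = TRUE) {
  data <- tibble::as_tibble(data)
  need <- c(id, time, outcome, covariates)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "hsuv_data_error")
  }
  cc <- complete.cases(data[need])
  n_drop_rows <- sum(!cc)
  drop_pat <- setdiff(unique(data[[id]][!cc]), unique(data[[id]][cc]))
  if (n_drop_rows > 0) {
    inform(sprintf(
      "Dropped %d row(s) with missing values (%d patient(s) excluded entirely).",
      n_drop_rows, length(drop_pat)))
  }
  data <- data[cc, , drop = FALSE]
  if (nrow(data) == 0) abort("No complete rows.", class = "hsuv_data_error")
  u <- data[[outcome]]
  if (check_range && any(u < spec$u_min - 1e-9 | u > spec$u_max + 1e-9)) {
    abort(sprintf("Utilities outside [%g, %g].", spec$u_min, spec$u_max),
          class = "hsuv_data_error")
  }
  tb <- time_basis(data[[time]], knot = knot)
  Xcov <- as.matrix(data[covariates])
  if (center_age && "age" %in% covariates) {
    Xcov[, "age"] <- Xcov[, "age"] - mean(Xcov[, "age"])
  }
  X <- cbind(`(Intercept)` = 1, Xcov, t_pre = tb$t_pre, t_post = tb$t_post)
  storage.mode(X) <- "double"
  pid <- match(data[[id]], unique(data[[id]]))
  list(u = u, X = X, pid = pid, m = max(pid),
       n = nrow(data), tpre = tb$t_pre, tpost = tb$t_post,
       time = data[[time]], patient_ids = unique(data[[id]]),
       covariates = covariates, knot = knot, spec = spec,
       n_dropped_rows = n_drop_rows, n_dropped_patients = length(drop_pat))
}

coef_names <- function(covariates) {
  c("(Intercept)", covariates, "t_pre", "t_post")
}
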