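# Likelihood-ratio covariate selection: a univariate screen at p < 0.20
# followed by forward selection at p < 0.05, run within one model family.
# Candidates only ever alter the fixed effects; the random structure and the
# time basis stay fixed, so the LRT reference is an ordinary chi-square with
# df = number of added coefficients (2 for the two-part family, which adds
# the covariate to both parts).

fit_for_selection <- function(data, family, covariates, ...) {
  fit_hsuv(data, family = family, covariates = covariates,
           compute_se = FALSE, ...)
}

candidate_df <- function(family) if (family == "twopart_beta") 2L else 1L

#' Univariate screen of candidate covariates
#'
#' Fits the base model (intercept, the two time slopes and the random
#' effects) and, for each candidate, the base model plus that single
#' candidate; candidates with a likelihood-ratio p-value below
#' `p_enter` pass the screen. Non-convergent candidates are flagged and
#' excluded.
#'
#' @param data Cohort data.
#' @param family Model family.
#' @param candidates Character vector of candidate covariate columns.
#' @param p_enter Screening threshold (default 0.20).
#' @param ... Passed to [fit_hsuv()] (e.g. `re_slope`, `nodes`).
#' @return A tibble with one row per candidate: LRT statistic, df, p-value
#'   and the screen verdict; base log-likelihood in attribute `"ll_base"`.
#' @export
univariate_screen <- function(data, family = "lmm",
                              candidates = candidate_covariates(),
                              p_enter = 0.20, ...) {
  base <- fit_for_selection(data, family, character(0), ...)
  df <- candidate_df(family)
  rows <- purrr::map(candidates, function(cand) {
    fit <- tryCatch(fit_for_selection(data, family, cand, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(candidate = cand, lrt = NA_real_, df = df,
                            p_value = NA_real_, retained = FALSE,
                            note = "non-convergent"))
    }
    lrt <- max(2 * (fit$loglik - base$loglik), 0)
    p <- pchisq(lrt, df = df, lower.tail = FALSE)
    tibble::tibble(candidate = cand, lrt = lrt, df = df, p_value = p,
                   retained = p < p_enter, note = "")
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "ll_base") <- base$loglik
  out
}

#' Forward selection among screened candidates
#'
#' Starting from the base model, repeatedly adds the screened candidate with
#' the smallest likelihood-ratio p-value against the current model, while
#' that p-value is below `p_stay`. Ties are broken by candidate order.
#'
#' @inheritParams univariate_screen
#' @param screened Character vector of candidates that passed the screen
#'   (e.g. `dplyr::filter(univariate_screen(...), retained)$candidate`).
#' @param p_stay Entry threshold for the forward steps (default 0.05).
#' @return A list with `selected` (character vector, in entry order),
#'   `steps` (tibble log of every evaluation) and `final_fit`.
#' @export
forward_select <- function(data, family = "lmm", screened,
                           p_stay = 0.05, ...) {
  current <- character(0)
  fit_cur <- fit_for_selection(data, family, current, ...)
  df <- candidate_df(family)
  remaining <- screened
  steps <- list()
  while (length(remaining) > 0) {
    evals <- purrr::map(remaining, function(cand) {
      fit <- tryCatch(fit_for_selection(data, family, c(current, cand), ...),
                      error = function(e) NULL)
      if (is.null(fit)) return(list(p = NA_real_, ll = NA_real_, fit = NULL))
      lrt <- max(2 * (fit$loglik - fit_cur$loglik), 0)
      list(p = pchisq(lrt, df = df, lower.tail = FALSE),
           ll = fit$loglik, fit = fit)
    })
    ps <- vapply(evals, function(e) e$p %||% NA_real_, numeric(1))
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = length(steps) + 1L, candidate = remaining, p_value = ps,
      loglik = vapply(evals, function(e) e$ll, numeric(1)))
    if (all(is.na(ps)) || min(ps, na.rm = TRUE) >= p_stay) break
    best <- which.min(replace(ps, is.na(ps), Inf))   # first minimum wins ties
    current <- c(current, remaining[best])
    fit_cur <- evals[[best]]$fit
    remaining <- remaining[-best]
  }
  list(selected = current,
       steps = if (length(steps)) dplyr::bind_rows(steps) else
         tibble::tibble(step = integer(), candidate = character(),
                        p_value = numeric(), loglik = numeric()),
       final_fit = fit_cur)
}

#' Run the full two-stage covariate selection
#'
#' Convenience wrapper: univariate screen at `p_enter`, then forward
#' selection at `p_stay`, returning a reproducible trace.
#'
#' @inheritParams univariate_screen
#' @param p_stay Forward-selection threshold.
#' @return A list with `screen` (tibble), `selected`, `steps`, `final_fit`.
#' @export
select_covariates <- function(data, family = "lmm",
                              candidates = candidate_covariates(),
                              p_enter = 0.20, p_stay = 0.05, ...) {
  scr <- univariate_screen(data, family, candidates, p_enter, ...)
  kept <- scr$candidate[scr$retained]
  fw <- forward_select(data, family, kept, p_stay, ...)
  c(list(screen = scr), fw)
}

#' Choose the number of ALDVMM latent classes by BIC
#'
#' Fits the ALDVMM for each candidate class count and retains the one with
#' the lowest BIC. Non-convergent fits are reported but excluded from the
#' choice.
#'
#' @inheritParams univariate_screen
#' @param covariates Fixed-effect covariates of every fit.
#' @param K_values Class counts to try (default 1 and 2).
#' @param ... Passed to [fit_hsuv()] (e.g. `multi_start`, `seed`, `psi1`).
#' @return A list with `K` (chosen count), `table` (per-K BIC tibble) and
#'   `fits` (list of `hsuv_fit`, one per converged K).
#' @export
select_aldvmm_classes <- function(data, covariates = default_covariates(),
                                  K_values = c(1, 2), ...) {
  fits <- purrr::map(K_values, function(k) {
    tryCatch(fit_hsuv(data, family = "aldvmm", covariates = covariates,
                      K = k, compute_se = FALSE, ...),
             error = function(e) NULL)
  })
  tab <- tibble::tibble(
    K = K_values,
    converged = !vapply(fits, is.null, logical(1)),
    logLik = vapply(fits, function(f) f$loglik %||% NA_real_, numeric(1)),
    BIC = vapply(fits, function(f) f$bic %||% NA_real_, numeric(1)))
  ok <- which(tab$converged)
  if (length(ok) == 0) {
    abort("No ALDVMM class count converged.",
          class = "hsuv_convergence_error")
  }
  chosen <- ok[which.min(tab$BIC[ok])]
  list(K = tab$K[chosen], table = tab, fits = fits[!vapply(fits, is.null,
                                                           logical(1))])
}
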