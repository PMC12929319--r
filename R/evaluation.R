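#' Precision metrics of utility predictions
#'
#' Root mean squared error, mean absolute error and the prediction range
#' (minimum and maximum predicted utility).
#'
#' @param observed Numeric vector of observed utilities.
#' @param predicted Numeric vector of predicted utilities (same length).
#' @return One-row tibble: `rmse`, `mae`, `pred_min`, `pred_max`, `n`.
#' @export
precision_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    abort("`observed` and `predicted` must be equal-length, non-empty.",
          class = "hsuv_data_error")
  }
  e <- observed - predicted
  tibble::tibble(rmse = sqrt(mean(e^2)), mae = mean(abs(e)),
                 pred_min = min(predicted), pred_max = max(predicted),
                 n = length(e))
}

#' Decile calibration of utility predictions
#'
#' Partitions observations into ten groups by deciles of the predicted
#' values (ties broken by stable rank), computes the mean observed and mean
#' predicted utility per group, and regresses the ten observed means on the
#' ten predicted means by ordinary least squares. Perfect calibration gives
#' an intercept of 0 and a slope of 1. Aberrant deciles are flagged by
#' externally studentized residuals (|r| > 2.5) or Cook's distance (> 0.5)
#' on the ten-point regression; at most `max_excluded` are dropped and the
#' line refit once.
#'
#' @param observed,predicted Numeric vectors (length >= 10).
#' @param max_excluded Maximum number of outlying deciles to exclude.
#' @return An object of class `hsuv_calibration`: a list with the per-decile
#'   table, `beta0`, `beta1`, and `excluded` decile indices.
#' @export
calibration_deciles <- function(observed, predicted, max_excluded = 2) {
  n <- length(observed)
  if (n < 10 || length(predicted) != n) {
    abort("Calibration needs >= 10 paired observations.",
          class = "hsuv_data_error")
  }
  decile <- dplyr::ntile(rank(predicted, ties.method = "first"), 10)
  tab <- tibble::tibble(decile = decile, observed = observed,
                        predicted = predicted) |>
    dplyr::group_by(.data$decile) |>
    dplyr::summarise(mean_predicted = mean(.data$predicted),
                     mean_observed = mean(.data$observed),
                     n = dplyr::n(), .groups = "drop")
  fit <- lm(mean_observed ~ mean_predicted, data = tab)
  if (suppressWarnings(summary(fit)$sigma) < 1e-9) {
    # numerically perfect line: influence measures are 0/0 noise
    flagged <- integer(0)
  } else {
    rs <- suppressWarnings(rstudent(fit))
    cd <- suppressWarnings(cooks.distance(fit))
    flagged <- which(abs(rs) > 2.5 | cd > 0.5)
  }
  if (length(flagged) > max_excluded) {
    flagged <- flagged[order(-abs(rstudent(fit)[flagged]))][seq_len(max_excluded)]
  }
  excluded <- tab$decile[flagged]
  if (length(flagged) > 0) {
    fit <- lm(mean_observed ~ mean_predicted, data = tab[-flagged, ])
  }
  if (nrow(tab) - length(flagged) < 3) {
    abort("Fewer than 3 deciles remain for the calibration line.",
          class = "hsuv_degenerate_error")
  }
  structure(list(
    table = dplyr::mutate(tab, excluded = .data$decile %in% excluded),
    beta0 = unname(coef(fit)[1]), beta1 = unname(coef(fit)[2]),
    excluded = excluded), class = "hsuv_calibration")
}

#' @export
print.hsuv_calibration <- function(x, ...) {
  cat(sprintf("Decile calibration: intercept %.3f, slope %.3f\n",
              x$beta0, x$beta1))
  if (length(x$excluded)) {
    cat("  Excluded decile(s):", paste(x$excluded, collapse = ", "), "\n")
  }
  print(x$table)
  invisible(x)
}

#' @method tidy hsuv_calibration
#' @export
tidy.hsuv_calibration <- function(x, ...) x$table

#' @method glance hsuv_calibration
#' @export
glance.hsuv_calibration <- function(x, ...) {
  tibble::tibble(beta0 = x$beta0, beta1 = x$beta1,
                 n_excluded = length(x$excluded))
}

#' Evaluate a fitted model on a cohort
#'
#' Computes fixed-effect-only predictions (`mode = "conditional_b0"`, the
#' scale on which the headline precision figures are reported), precision
#' metrics and the decile calibration in one call.
#'
#' @param fit An `hsuv_fit`.
#' @param data Cohort data (defaults must contain the model covariates,
#'   `time` and `hsuv`).
#' @param mode Prediction mode passed to [predict.hsuv_fit()].
#' @return A list with elements `metrics` (tibble) and `calibration`
#'   (`hsuv_calibration`).
#' @export
evaluate_fit <- function(fit, data, mode = "conditional_b0") {
  data <- tibble::as_tibble(data)
  cc <- complete.cases(data[c(fit$covariates, "time", "hsuv")])
  data <- data[cc, , drop = FALSE]
  pred <- predict(fit, data, mode = mode)
  list(metrics = precision_metrics(data$hsuv, pred),
       calibration = calibration_deciles(data$hsuv, pred))
}
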