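#' Calibration plot: observed versus predicted decile means
#'
#' Plots the ten decile means with the identity (perfect-calibration) line
#' and the fitted calibration line; excluded deciles are hollow.
#'
#' @param object An `hsuv_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsuv_calibration
#' @export
autoplot.hsuv_calibration <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mean_predicted,
                                    y = .data$mean_observed)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, colour = "darkgreen") +
    ggplot2::geom_abline(intercept = object$beta0, slope = object$beta1,
                         linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2.5) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "Mean predicted HSUV (decile group)",
      y = "Mean observed HSUV",
      title = sprintf("Decile calibration: intercept %.3f, slope %.3f",
                      object$beta0, object$beta1)) +
    ggplot2::theme_minimal()
}

#' Plot predicted utility trajectories
#'
#' @param object Output of [predict_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hsuv_trajectory
#' @export
autoplot.hsuv_trajectory <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$time, y = .data$hsuv_pred,
                               group = factor(.data$profile),
                               colour = factor(.data$profile))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "Years since transplantation",
                  y = "Predicted HSUV", colour = "Profile") +
    ggplot2::theme_minimal()
}
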