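#' Plot a calibration fit
#'
#' Replicate responses against concentration with the fitted line and the
#' rendered equation and R-squared in the subtitle.
#'
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_fit <- function(object, ...) {
  df <- tibble::tibble(
    level = object$lm$model$level,
    response = object$lm$model$response
  )
  lbl <- if (!is.na(object$analyte)) {
    sprintf("%s (%s)", object$analyte, object$matrix)
  } else {
    "Calibration"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$response)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      title = lbl,
      subtitle = sprintf("y = %.5gx %s %.5g,  R² = %.4f",
                         object$slope,
                         ifelse(object$intercept < 0, "-", "+"),
                         abs(object$intercept), object$r_squared),
      x = "Concentration (mg/L)", y = "Peak area"
    ) +
    ggplot2::theme_minimal()
}

#' Matrix-effect overview plot
#'
#' Mean absolute matrix effect per analyte, matrix and spike level with the
#' acceptance band shaded; points outside the band are ionization
#' suppression/enhancement findings.
#'
#' @param me Output of [assess_matrix_effect()].
#' @param bands An [acceptance_bands()] object (for the shaded band).
#' @return A ggplot.
#' @export
plot_matrix_effect <- function(me, bands = acceptance_bands()) {
  ggplot2::ggplot(
    me,
    ggplot2::aes(x = .data$analyte, y = .data$me_mean,
                 colour = factor(.data$level_mg_per_L))
  ) +
    ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = bands$me_range[1], ymax = bands$me_range[2],
      alpha = 0.12, fill = "seagreen"
    ) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~matrix) +
    ggplot2::labs(x = NULL, y = "%ME (absolute matrix effect)",
                  colour = "Spike (mg/L)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Recovery overview plot
#'
#' Percent recovery per analyte, matrix and spike level with the acceptance
#' band shaded.
#'
#' @param pa Output of [assess_precision_accuracy()].
#' @param bands An [acceptance_bands()] object.
#' @return A ggplot.
#' @export
plot_recovery <- function(pa, bands = acceptance_bands()) {
  ggplot2::ggplot(
    pa,
    ggplot2::aes(x = .data$analyte, y = .data$recovery,
                 colour = factor(.data$level_mg_per_L))
  ) +
    ggplot2::annotate(
      "rect", xmin = -Inf, xmax = Inf,
      ymin = bands$recovery_range[1], ymax = bands$recovery_range[2],
      alpha = 0.12, fill = "seagreen"
    ) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey40") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~matrix) +
    ggplot2::labs(x = NULL, y = "% recovery", colour = "Spike (mg/L)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
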