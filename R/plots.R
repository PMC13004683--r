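#' Plot a clock curve
#'
#' Biomarker value against years from positivity, with the anchor marked.
#'
#' @param object A `clock_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clock_curve <- function(object, ...) {
  anchor <- attr(object, "anchor")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$years_from_positivity,
                                       y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = anchor, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Years from biomarker positivity",
                  y = "Biomarker value",
                  title = paste0(attr(object, "method"), " clock model")) +
    ggplot2::theme_minimal()
}

#' Plot a rate-versus-level curve
#'
#' Fitted mean rate of change with a pointwise ~95% band (fit +/- 2 SE).
#'
#' @param object A `rate_curve`.
#' @param rates Optional tibble of individual rates to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_curve <- function(object, rates = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$rate))
  if (!is.null(rates)) {
    p <- p + ggplot2::geom_point(
      data = rates, ggplot2::aes(x = .data$midpoint_value, y = .data$rate),
      colour = "grey60", alpha = 0.6)
  }
  p +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$rate - 2 * .data$pred_se,
                                      ymax = .data$rate + 2 * .data$pred_se),
                         fill = "grey80", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Biomarker value at midpoint of follow-up",
                  y = "Rate of change (units/year)") +
    ggplot2::theme_minimal()
}

#' Plot an onset model
#'
#' Observed onset age against estimated positivity age with the fitted line
#' and the identity line for reference.
#'
#' @param object An `onset_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.onset_model <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$positivity_age,
                                            y = .data$onset_age)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue") +
    ggplot2::labs(x = "Estimated age at biomarker positivity (years)",
                  y = "Age at symptom onset (years)") +
    ggplot2::theme_minimal()
}

#' Step plot of Kaplan-Meier curves
#'
#' @param km Tibble from [kaplan_meier()].
#' @param xlab X-axis label (name the timescale in use).
#' @return A ggplot.
#' @export
plot_kaplan_meier <- function(km, xlab = "Time (years)") {
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = xlab, y = "Probability cognitively unimpaired",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Raster plot of longitudinal diagnoses on the positivity timescale
#'
#' One row per subject, ordered by estimated positivity age; each point is
#' one clinical assessment placed at years from estimated positivity and
#' coloured by the subject's diagnostic group.
#'
#' @param clinical Clinical tibble.
#' @param positivity Tibble with `subject_id`, `estimated_age`.
#' @param groups Tibble from [classify_diagnostic_group()].
#' @return A ggplot.
#' @export
plot_diagnosis_raster <- function(clinical, positivity, groups) {
  df <- clinical |>
    dplyr::inner_join(positivity[, c("subject_id", "estimated_age")],
                      by = "subject_id") |>
    dplyr::inner_join(groups, by = "subject_id") |>
    dplyr::mutate(tau = .data$age - .data$estimated_age,
                  impaired = .data$cdr > 0)
  ord <- df |>
    dplyr::distinct(.data$subject_id, .data$estimated_age) |>
    dplyr::arrange(.data$estimated_age)
  df$subject_id <- factor(df$subject_id, levels = ord$subject_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$subject_id,
                                   colour = .data$group,
                                   shape = .data$impaired)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Years from estimated biomarker positivity",
                  y = "Subjects (ordered by positivity age)",
                  colour = NULL, shape = "Impaired") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
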