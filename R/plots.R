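#' Plot a Kaplan-Meier curve
#'
#' @param object A [km_estimate()] result.
#' @param ... Unused.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- tibble(time = c(0, object$time), survival = c(1, object$survival))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot an STC prediction, optionally against the comparator's KM curve
#'
#' @param object A [predict_at_population()] result.
#' @param comparator_km Optional [km_estimate()] of the comparator
#'   pseudo-IPD to overlay.
#' @param ... Unused.
#' @export
autoplot.stc_prediction <- function(object, comparator_km = NULL, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_line(ggplot2::aes(colour = "STC prediction (index)")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL,
                  title = sprintf("Index treatment predicted in the %s population",
                                  object$population$trial_label)) +
    ggplot2::theme_minimal()
  if (!is.null(comparator_km)) {
    kdf <- tibble(time = c(0, comparator_km$time),
                  survival = c(1, comparator_km$survival))
    p <- p + ggplot2::geom_step(data = kdf,
                                ggplot2::aes(colour = "Comparator KM"))
  }
  p
}

#' Forest-style plot of landmark hazard ratios
#'
#' @param object A [bootstrap_compare()] result.
#' @param ... Unused.
#' @export
autoplot.stc_effect <- function(object, ...) {
  hr <- filter(object$estimates, grepl("^hr_", .data$estimand))
  ggplot2::ggplot(hr, ggplot2::aes(x = factor(.data$time), y = .data$median)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$conf_low,
                                        ymax = .data$conf_high), width = 0.15) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Landmark (months)", y = "Hazard ratio (index / comparator)",
                  title = sprintf("vs %s", object$comparator_label)) +
    ggplot2::theme_minimal()
}
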