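#' Align a selected covariate set with what a comparator reports
#'
#' A covariate selected on the index IPD can only be used in a comparison
#' if the comparator trial reported its aggregate value. This returns the
#' selected covariates that the baseline reports, preserving order. The
#' model must then be REFIT on the reduced set before prediction -- so
#' different comparators can legitimately use different regression models.
#'
#' @param selected Character vector of selected covariate names.
#' @param baseline An [aggregate_baseline()].
#' @return Character vector: `selected` intersected with the reported
#'   covariates.
#' @export
align_covariates <- function(selected, baseline) {
  stopifnot(inherits(baseline, "aggregate_baseline"))
  selected[selected %in% names(baseline$values)]
}

#' Predict the index treatment's survival curve in a comparator population
#'
#' The STC plug-in: evaluate the fitted covariate-adjusted model at the
#' comparator's aggregate (mean) covariate values. For AFT families the
#' acceleration factor is `theta = exp(mu + (Xbar - centering) . beta)` and
#' the curve is `S0(t * theta)`; for splines the linear-predictor shift is
#' added to `s(log t, gamma)` before inverting the link; for Gompertz the
#' baseline hazard is multiplied by `exp(lp)`. Prediction is at mean
#' covariate values only (no population integration), matching the method.
#'
#' @param model A converged [stc_model()] whose covariates are all reported
#'   by `baseline` (use [align_covariates()] and refit first).
#' @param baseline An [aggregate_baseline()].
#' @param times Evaluation grid; defaults to `grid_points` equally spaced
#'   times over `[0, follow_up]`.
#' @param grid_points Grid density for the default grid.
#' @param dropped_covariates Names of originally selected covariates that
#'   were dropped because this comparator does not report them (recorded
#'   for the run manifest).
#' @return An object of class `stc_prediction`: the model, population,
#'   linear-predictor value and the predicted curve as a tibble.
#' @export
predict_at_population <- function(model, baseline, times = NULL,
                                  grid_points = 1000,
                                  dropped_covariates = character()) {
  stopifnot(inherits(model, "stc_model"), inherits(baseline, "aggregate_baseline"))
  missing <- setdiff(model$covariates, names(baseline$values))
  if (length(missing) > 0) {
    abort(sprintf(paste0("covariate '%s' in the model is not reported by '%s'; ",
                         "run align_covariates() and refit before predicting"),
                  missing[1], baseline$trial_label),
          class = "stc_covariate_error")
  }
  if (any(dropped_covariates %in% model$covariates)) {
    abort("dropped covariates must not appear in the model", class = "stc_covariate_error")
  }
  xbar <- baseline$values[model$covariates]
  lp <- linear_predictor(model, xbar)
  if (is.null(times)) times <- seq(0, baseline$follow_up, length.out = grid_points)
  curve <- tibble(time = times, survival = model_survival(model, xbar, times))
  structure(list(model = model, population = baseline, lp_value = lp,
                 xbar = xbar, curve = curve,
                 dropped_covariates = dropped_covariates),
            class = "stc_prediction")
}

#' @export
print.stc_prediction <- function(x, ...) {
  cat(sprintf("STC prediction at '%s' population (follow-up %.1f months)\n",
              x$population$trial_label, x$population$follow_up))
  cat(sprintf("  model: %s%s | lp = %.4f\n", x$model$family,
              if (x$model$family == "spline") paste0(" (", x$model$link, ")") else "",
              x$lp_value))
  if (length(x$dropped_covariates)) {
    cat("  dropped (unreported) covariates:",
        paste(x$dropped_covariates, collapse = ", "), "\n")
  }
  invisible(x)
}

# survival of a prediction at arbitrary times (analytic, not interpolated)
prediction_survival <- function(pred, t) {
  model_survival(pred$model, pred$xbar, t)
}

# hazard of a prediction at arbitrary times
prediction_hazard <- function(pred, t) {
  model_hazard(pred$model, pred$xbar, t)
}
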