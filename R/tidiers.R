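#' Tidy a fitted survival model
#'
#' One row per free parameter: baseline distribution parameters (or spline
#' coefficients) then covariate coefficients, with standard errors where
#' available. Covariate terms are on the package's log time-acceleration
#' (AFT) / log hazard-multiplier (Gompertz) / linear-predictor (spline)
#' scale.
#'
#' @param x An [stc_model()].
#' @param ... Unused.
#' @export
tidy.stc_model <- function(x, ...) {
  base_terms <- if (x$family == "spline") {
    tibble(term = paste0("gamma", seq_along(x$gamma) - 1),
           estimate = x$gamma, type = "spline")
  } else {
    tibble(term = names(x$baseline), estimate = unname(x$baseline),
           type = "baseline")
  }
  cov_terms <- if (length(x$beta)) {
    tibble(term = names(x$beta), estimate = unname(x$beta),
           std.error = x$beta_se, type = "covariate")
  } else NULL
  bind_rows(base_terms, cov_terms)
}

#' @rdname tidy.stc_model
#' @export
glance.stc_model <- function(x, ...) {
  tibble(family = x$family, link = x$link,
         n_knots = max(length(x$knots) - 2L, 0L),
         n = x$n, n_event = x$n_event,
         n_params = x$n_params, logLik = x$loglik, AIC = x$aic,
         converged = x$converged)
}

#' Tidy an STC comparison
#'
#' One row per estimand (RMST index / comparator / difference, and one
#' landmark HR per time) with the bootstrap median, percentile interval
#' and one-sided p-value.
#'
#' @param x An [bootstrap_compare()] result.
#' @param ... Unused.
#' @export
tidy.stc_effect <- function(x, ...) {
  mutate(x$estimates,
         comparator = x$comparator_label, tau = x$tau,
         model = if (x$naive) "naive_km" else {
           paste0(x$spec$family,
                  ifelse(is.na(x$spec$link %||% NA), "", paste0("_", x$spec$link)))
         },
         .before = 1)
}

#' @rdname tidy.stc_effect
#' @export
glance.stc_effect <- function(x, ...) {
  tibble(comparator = x$comparator_label, tau = x$tau, B = x$B,
         B_used = x$B_used, n_dropped = x$n_dropped, seed = x$seed,
         naive = x$naive)
}
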