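#' Construct a fitted (or hand-specified) survival model object
#'
#' The container for all survival models in the package: standard
#' parametric families, the Gompertz proportional-hazards model and
#' Royston-Parmar splines. Fitted models are produced by
#' [fit_parametric()] and [fit_spline()]; the constructor is exported so
#' known-truth models can be built directly in simulations and tests.
#'
#' @param family One of `r paste(stc_family_names(), collapse = ", ")` or
#'   `"spline"`.
#' @param baseline Named numeric vector of natural-scale baseline
#'   distribution parameters (empty for splines).
#' @param beta Named numeric vector of covariate coefficients on the
#'   log time-acceleration scale (AFT families: positive values shorten
#'   survival), the log hazard-multiplier scale (Gompertz), or additive on
#'   the linear predictor (splines).
#' @param mu Intercept of the linear predictor (0 for fitted models, where
#'   the intercept is absorbed into the baseline parameters / `gamma[1]`).
#' @param link Spline link: `"hazard"`, `"odds"` or `"normal"`; `NA` for
#'   parametric families.
#' @param gamma Spline coefficients (gamma0, gamma1, then one per internal
#'   knot).
#' @param knots All knots in log time (boundary and internal), increasing.
#' @param centering Named numeric vector subtracted from covariates before
#'   applying `beta` (sample means of continuous covariates for fitted
#'   models).
#' @param loglik,n_params,aic,vcov,converged Fit metadata.
#' @param n,n_event Sample size and event count.
#' @param arm_label Data arm the model was fitted to.
#' @return An object of class `stc_model`.
#' @export
stc_model <- function(family, baseline = numeric(), beta = numeric(),
                      mu = 0, link = NA_character_, gamma = numeric(),
                      knots = numeric(), centering = NULL,
                      loglik = NA_real_, n_params = NA_integer_,
                      aic = NA_real_, vcov = NULL, converged = TRUE,
                      n = NA_integer_, n_event = NA_integer_,
                      arm_label = NA_character_) {
  if (family != "spline") .family_info(family)
  if (is.null(centering)) {
    centering <- setNames(rep(0, length(beta)), names(beta))
  }
  if (is.na(aic) && !is.na(loglik) && !is.na(n_params)) {
    aic <- -2 * loglik + 2 * n_params
  }
  structure(list(family = family, link = link, knots = knots,
                 mu = mu, gamma = gamma, beta = beta,
                 baseline = baseline, centering = centering,
                 loglik = loglik, n_params = n_params, aic = aic,
                 vcov = vcov, converged = converged,
                 covariates = names(beta) %||% character(),
                 n = n, n_event = n_event, arm_label = arm_label,
                 beta_se = rep(NA_real_, length(beta))),
            class = "stc_model")
}

#' @export
print.stc_model <- function(x, ...) {
  lab <- if (x$family == "spline") {
    sprintf("Royston-Parmar spline (%d internal knot(s), %s link)",
            max(length(x$knots) - 2L, 0L), x$link)
  } else x$family
  cat("Survival model:", lab, "\n")
  cat(sprintf("  covariates: %s\n",
              if (length(x$beta)) paste(names(x$beta), collapse = ", ") else "(none)"))
  if (!is.na(x$loglik)) {
    cat(sprintf("  loglik %.3f | AIC %.3f | params %d | converged %s\n",
                x$loglik, x$aic, x$n_params, x$converged))
  }
  invisible(x)
}

# normalise covariate input: named numeric vector from vector / list /
# single-row data frame
.covariate_vector <- function(newdata) {
  if (is.data.frame(newdata)) {
    stopifnot(nrow(newdata) == 1)
    newdata <- unlist(newdata[1, , drop = TRUE])
  }
  unlist(newdata) %||% numeric()
}

#' Linear predictor of a survival model at covariate values
#'
#' `mu + sum(beta_k * (X_k - centering_k))`: the log time-acceleration
#' factor for AFT families, the log hazard multiplier for Gompertz, and the
#' additive intercept shift for splines.
#'
#' @param model An [stc_model()].
#' @param newdata Named numeric vector, list or single-row data frame
#'   providing every model covariate.
#' @return A single number.
#' @export
linear_predictor <- function(model, newdata = NULL) {
  if (length(model$beta) == 0) return(model$mu)
  x <- .covariate_vector(newdata)
  missing <- setdiff(names(model$beta), names(x))
  if (length(missing) > 0) {
    abort(sprintf("covariate '%s' required by the model is missing", missing[1]),
          class = "stc_covariate_error")
  }
  cen <- model$centering[names(model$beta)]
  cen[is.na(cen)] <- 0
  model$mu + sum(model$beta * (x[names(model$beta)] - cen))
}

#' Survival and hazard of AFT-family models
#'
#' `aft_survival()` evaluates S(t | X) = S0(t * theta) with
#' theta = exp(linear predictor); `aft_hazard()` evaluates
#' theta * h0(t * theta). Gompertz (a proportional-hazards family) is
#' rejected by `aft_survival()` but routed through `aft_hazard()` as
#' exp(lp) * h0(t).
#'
#' @inheritParams linear_predictor
#' @param t Time(s) in months (`>= 0` for survival, `> 0` for hazard).
#' @return Numeric vector the length of `t`.
#' @export
aft_survival <- function(model, newdata = NULL, t) {
  info <- .family_info(model$family)
  if (!info$aft) {
    abort(sprintf("'%s' is not an AFT family", model$family), class = "stc_family_error")
  }
  stopifnot(all(t >= 0))
  theta <- exp(linear_predictor(model, newdata))
  .baseline_survival(model$family, t * theta, model$baseline)
}

#' @rdname aft_survival
#' @export
aft_hazard <- function(model, newdata = NULL, t) {
  if (any(t <= 0)) abort("hazard requires t > 0", class = "stc_validation_error")
  info <- .family_info(model$family)
  lp <- linear_predictor(model, newdata)
  if (!info$aft) {
    # proportional hazards (Gompertz)
    return(exp(lp) * .baseline_hazard(model$family, t, model$baseline))
  }
  theta <- exp(lp)
  theta * .baseline_hazard(model$family, t * theta, model$baseline)
}

#' Survival / hazard for any fitted model type
#'
#' Family-dispatching wrappers used by the STC prediction and estimand
#' code: AFT families via [aft_survival()], Gompertz via its
#' proportional-hazards form, splines via [spline_survival()].
#'
#' @inheritParams aft_survival
#' @export
model_survival <- function(model, newdata = NULL, t) {
  if (model$family == "spline") return(spline_survival(model, newdata, t))
  info <- .family_info(model$family)
  if (info$aft) return(aft_survival(model, newdata, t))
  # Gompertz PH: S(t|X) = S0(t)^exp(lp)
  stopifnot(all(t >= 0))
  lp <- linear_predictor(model, newdata)
  .baseline_survival(model$family, t, model$baseline)^exp(lp)
}

#' @rdname model_survival
#' @export
model_hazard <- function(model, newdata = NULL, t) {
  if (model$family == "spline") return(spline_hazard(model, newdata, t))
  aft_hazard(model, newdata, t)
}

# which covariates look continuous (anything not coded 0/1)
.continuous_covariates <- function(data, covariates) {
  covariates[vapply(covariates, function(cv) {
    v <- data[[cv]]
    !all(v %in% c(0, 1))
  }, logical(1))]
}

.centering_map <- function(data, covariates) {
  cen <- setNames(rep(0, length(covariates)), covariates)
  for (cv in .continuous_covariates(data, covariates)) cen[cv] <- mean(data[[cv]])
  cen
}

# run a flexsurv fit with jittered method-of-moments restarts; returns the
# fit or NULL after all attempts fail
.fit_with_restarts <- function(fit_fun, inits0, n_restarts = 5) {
  for (attempt in seq_len(n_restarts)) {
    inits <- if (attempt == 1) NULL else {
      jit <- inits0 * exp(stats::rnorm(length(inits0), 0, 0.2))
      zero <- inits0 == 0  # unconstrained parameters started at 0 jitter additively
      jit[zero] <- stats::rnorm(sum(zero), 0, 0.2)
      jit
    }
    f <- tryCatch(suppressWarnings(fit_fun(inits)), error = function(e) NULL)
    if (!is.null(f) && is.finite(f$loglik)) return(f)
  }
  NULL
}

#' Fit a covariate-adjusted parametric survival model by maximum likelihood
#'
#' Right-censored maximum likelihood for the standard parametric families
#' (exponential, Weibull, gamma, log-logistic, log-normal, generalized F --
#' all accelerated failure time -- plus the proportional-hazards Gompertz).
#' Continuous covariates are centered at their sample means before
#' optimisation (stored in `centering`; mathematically neutral, the
#' likelihood and coefficients are unchanged). Optimisation failures after
#' jittered restarts are returned flagged `converged = FALSE` rather than
#' raised, so model selection can filter them.
#'
#' @param data An [as_ipd()] dataset with at least one event.
#' @param family Family name, see [stc_family_names()].
#' @param covariates Covariate names to adjust for (subset of
#'   `ipd_covariates(data)`).
#' @return An [stc_model()].
#' @export
fit_parametric <- function(data, family, covariates = character()) {
  info <- .family_info(family)
  stopifnot(inherits(data, "stc_ipd"))
  if (!all(covariates %in% ipd_covariates(data))) {
    abort("covariates must be a subset of the dataset's covariates",
          class = "stc_covariate_error")
  }
  if (sum(data$event) < 1) {
    abort("all subjects are censored; cannot fit a survival model",
          class = "stc_validation_error")
  }
  cen <- .centering_map(data, covariates)
  d <- as.data.frame(data)
  for (cv in covariates) d[[cv]] <- d[[cv]] - cen[cv]
  fml <- if (length(covariates)) {
    stats::as.formula(paste("survival::Surv(time, event) ~",
                            paste(sprintf("`%s`", covariates), collapse = " + ")))
  } else survival::Surv(time, event) ~ 1
  fit_fun <- function(inits) {
    if (is.null(inits)) {
      flexsurv::flexsurvreg(fml, data = d, dist = info$dist)
    } else {
      flexsurv::flexsurvreg(fml, data = d, dist = info$dist,
                            inits = c(inits, rep(0, length(covariates))))
    }
  }
  inits0 <- .mom_inits(family, d)
  f <- .fit_with_restarts(fit_fun, inits0)
  if (is.null(f)) {
    return(stc_model(family, converged = FALSE,
                     beta = setNames(rep(NA_real_, length(covariates)), covariates),
                     centering = cen, n = nrow(d), n_event = sum(d$event),
                     arm_label = attr(data, "arm_label")))
  }
  est <- setNames(f$res[, "est"], rownames(f$res))
  base <- est[info$pars]
  beta <- if (length(covariates)) {
    info$beta_sign * est[covariates]
  } else numeric()
  names(beta) <- covariates
  conv <- isTRUE(f$opt$convergence == 0) && is.finite(f$loglik)
  m <- stc_model(family, baseline = base, beta = beta, mu = 0,
                 centering = cen, loglik = f$loglik,
                 n_params = f$npars, aic = f$AIC, vcov = f$cov,
                 converged = conv, n = nrow(d), n_event = sum(d$event),
                 arm_label = attr(data, "arm_label"))
  if (length(covariates)) {
    m$beta_se <- unname(f$res[covariates, "se"])
  }
  m
}
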