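# Survival family registry.
#
# Every accelerated failure time (AFT) family is characterised by its
# baseline survival S0 and hazard h0; covariates act through the time
# acceleration factor theta = exp(lp), S(t|X) = S0(t * theta). Gompertz is
# the one proportional-hazards family: h(t|X) = exp(lp) * h0(t). Package
# convention: positive coefficients shorten survival (beta = log(2) halves
# expected survival when the covariate increases by one).
#
# flexsurv places covariates on the location parameter of each
# distribution; `beta_sign` converts its coefficients to the package
# convention (scale/meanlog/mu-located families flip sign, rate-located
# families keep it).

.stc_families <- list(
  exponential = list(dist = "exp", aft = TRUE, beta_sign = 1,
                     pars = "rate"),
  weibull     = list(dist = "weibull", aft = TRUE, beta_sign = -1,
                     pars = c("shape", "scale")),
  gamma       = list(dist = "gamma", aft = TRUE, beta_sign = 1,
                     pars = c("shape", "rate")),
  loglogistic = list(dist = "llogis", aft = TRUE, beta_sign = -1,
                     pars = c("shape", "scale")),
  lognormal   = list(dist = "lnorm", aft = TRUE, beta_sign = -1,
                     pars = c("meanlog", "sdlog")),
  genf        = list(dist = "genf", aft = TRUE, beta_sign = -1,
                     pars = c("mu", "sigma", "Q", "P")),
  gompertz    = list(dist = "gompertz", aft = FALSE, beta_sign = 1,
                     pars = c("shape", "rate"))
)

#' Names of the supported parametric survival families
#'
#' Six accelerated failure time families plus the proportional-hazards
#' Gompertz (splines are handled separately by [fit_spline()]).
#' @export
stc_family_names <- function() names(.stc_families)

.family_info <- function(family) {
  info <- .stc_families[[family]]
  if (is.null(info)) {
    abort(sprintf("unknown survival family '%s'", family), class = "stc_family_error")
  }
  info
}

# baseline survival of an AFT (or Gompertz) family at its natural-scale
# parameters
.baseline_survival <- function(family, t, pars) {
  switch(family,
    exponential = exp(-pars[["rate"]] * t),
    weibull     = pweibull(t, pars[["shape"]], pars[["scale"]], lower.tail = FALSE),
    gamma       = pgamma(t, pars[["shape"]], pars[["rate"]], lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, pars[["shape"]], pars[["scale"]], lower.tail = FALSE),
    lognormal   = plnorm(t, pars[["meanlog"]], pars[["sdlog"]], lower.tail = FALSE),
    genf        = flexsurv::pgenf(t, pars[["mu"]], pars[["sigma"]], pars[["Q"]],
                                  pars[["P"]], lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, pars[["shape"]], pars[["rate"]], lower.tail = FALSE),
    abort(sprintf("unknown survival family '%s'", family), class = "stc_family_error")
  )
}

.baseline_hazard <- function(family, t, pars) {
  switch(family,
    exponential = rep(pars[["rate"]], length(t)),
    weibull     = flexsurv::hweibull(t, pars[["shape"]], pars[["scale"]]),
    gamma       = flexsurv::hgamma(t, pars[["shape"]], pars[["rate"]]),
    loglogistic = flexsurv::hllogis(t, pars[["shape"]], pars[["scale"]]),
    lognormal   = flexsurv::hlnorm(t, pars[["meanlog"]], pars[["sdlog"]]),
    genf        = flexsurv::hgenf(t, pars[["mu"]], pars[["sigma"]], pars[["Q"]], pars[["P"]]),
    gompertz    = flexsurv::hgompertz(t, pars[["shape"]], pars[["rate"]]),
    abort(sprintf("unknown survival family '%s'", family), class = "stc_family_error")
  )
}

# inverse baseline survival: t such that S0(t) = p
.baseline_quantile_surv <- function(family, p, pars) {
  switch(family,
    exponential = qweibull(p, 1, 1 / pars[["rate"]], lower.tail = FALSE),
    weibull     = qweibull(p, pars[["shape"]], pars[["scale"]], lower.tail = FALSE),
    gamma       = qgamma(p, pars[["shape"]], pars[["rate"]], lower.tail = FALSE),
    loglogistic = flexsurv::qllogis(p, pars[["shape"]], pars[["scale"]], lower.tail = FALSE),
    lognormal   = qlnorm(p, pars[["meanlog"]], pars[["sdlog"]], lower.tail = FALSE),
    genf        = flexsurv::qgenf(p, pars[["mu"]], pars[["sigma"]], pars[["Q"]],
                                  pars[["P"]], lower.tail = FALSE),
    gompertz    = flexsurv::qgompertz(p, pars[["shape"]], pars[["rate"]], lower.tail = FALSE),
    abort(sprintf("unknown survival family '%s'", family), class = "stc_family_error")
  )
}

# crude method-of-moments style starting values used for jittered restarts
.mom_inits <- function(family, data) {
  tt <- data$time[data$event == 1]
  if (length(tt) < 2) tt <- data$time
  m <- mean(tt); v <- max(stats::var(tt), 1e-6)
  lt <- log(tt)
  switch(family,
    exponential = c(rate = 1 / m),
    weibull     = c(shape = 1.2, scale = m),
    gamma       = c(shape = max(m^2 / v, 0.2), rate = max(m / v, 1e-4)),
    loglogistic = c(shape = 1.5, scale = median(tt)),
    lognormal   = c(meanlog = mean(lt), sdlog = max(stats::sd(lt), 0.1)),
    genf        = c(mu = mean(lt), sigma = max(stats::sd(lt), 0.1), Q = 0, P = 0.1),
    gompertz    = c(shape = 1e-3, rate = 1 / m)
  )
}
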