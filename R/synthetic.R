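#' Covariate generators for synthetic IPD
#'
#' @param p Bernoulli success probability.
#' @export
cov_bernoulli <- function(p) {
  stopifnot(p >= 0, p <= 1)
  list(type = "bernoulli", p = p)
}

#' @rdname cov_bernoulli
#' @param mean,sd Normal parameters.
#' @export
cov_normal <- function(mean, sd) {
  stopifnot(sd > 0)
  list(type = "normal", mean = mean, sd = sd)
}

# invert a spline model's survival for inverse-transform sampling
.spline_event_time <- function(u, gamma, knots, link, lp) {
  target <- .link_eta(link, u) - lp
  # s(u) is increasing in u for a valid model; bracket widely
  s_fun <- function(z) .spline_s(gamma, knots, z) - target
  lo <- knots[1] - 30; hi <- knots[length(knots)] + 30
  exp(uniroot(s_fun, c(lo, hi), extendInt = "upX", tol = 1e-10)$root)
}

#' Generate synthetic IPD with covariate-driven survival and censoring
#'
#' Event times are drawn by inverse transform from the chosen family:
#' `T = S0^{-1}(U) / theta_i` for AFT families with
#' `theta_i = exp(mu + X_i . beta)`, the proportional-hazards analogue for
#' Gompertz, and numeric link inversion for splines. Observed time is the
#' minimum of the event time, an administrative cutoff and an exponential
#' random censoring time.
#'
#' @param n Number of subjects.
#' @param family Survival family (see [stc_family_names()]) or `"spline"`.
#' @param params Named list of natural-scale baseline parameters (for
#'   `"spline"`: `gamma`, `knots` in log time, and `link`).
#' @param beta Named covariate coefficients (package convention: positive
#'   values shorten survival).
#' @param covariates Named list of [cov_bernoulli()] / [cov_normal()]
#'   specifications; must cover `names(beta)`.
#' @param mu Intercept of the log acceleration factor.
#' @param censoring Length-2 numeric: administrative cutoff time (months,
#'   may be `Inf`) and exponential random-censoring rate (0 for none).
#' @param seed Optional integer seed.
#' @param arm_label Arm label.
#' @return An [as_ipd()] dataset.
#' @export
generate_ipd <- function(n, family = "weibull",
                         params = list(shape = 1.2, scale = 30),
                         beta = numeric(), covariates = list(), mu = 0,
                         censoring = c(admin = Inf, rate = 0),
                         seed = NULL, arm_label = "synthetic") {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!all(names(beta) %in% names(covariates))) {
    abort("every coefficient in beta needs a covariate generator",
          class = "stc_validation_error")
  }
  X <- tibble(.rows = n)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    X[[nm]] <- switch(cv$type,
      bernoulli = rbinom(n, 1, cv$p),
      normal = rnorm(n, cv$mean, cv$sd),
      abort(sprintf("unknown covariate type '%s'", cv$type)))
  }
  lp <- rep(mu, n)
  if (length(beta)) lp <- lp + as.matrix(X[names(beta)]) %*% beta
  lp <- drop(lp)
  u <- runif(n)
  t_event <- if (family == "spline") {
    vapply(seq_len(n), function(i) {
      .spline_event_time(u[i], params$gamma, params$knots, params$link, lp[i])
    }, numeric(1))
  } else {
    info <- .family_info(family)
    pars <- unlist(params)
    if (info$aft) {
      .baseline_quantile_surv(family, u, pars) / exp(lp)
    } else {
      # Gompertz PH: S(t|X) = S0(t)^theta  =>  S0(t) = u^(1/theta)
      .baseline_quantile_surv(family, u^exp(-lp), pars)
    }
  }
  admin <- censoring[[1]]
  rate <- censoring[[2]]
  t_cens <- if (rate > 0) pmin(rexp(n, rate), admin) else rep(admin, n)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)
  time <- pmax(time, 1e-9)
  df <- dplyr::bind_cols(tibble(time = time, event = event), X)
  as_ipd(df, covariates = names(covariates), arm_label = arm_label)
}

#' Render a simulated arm the way a publication would report it
#'
#' Computes the KM curve, samples it at `curve_points` equally spaced
#' times (optionally adding bounded uniform digitization jitter, then
#' re-monotonizing), tabulates numbers at risk at multiples of
#' `risk_interval`, and summarises covariates into an
#' [aggregate_baseline()] (proportions for binary covariates, the median
#' for continuous ones), so the Guyot reconstruction and covariate
#' alignment stages can be exercised without any real published data.
#'
#' @param data An [as_ipd()] dataset.
#' @param curve_points Number of digitized coordinates (>= 10).
#' @param risk_interval Risk-table spacing in months.
#' @param jitter Half-width of uniform digitization error on survival
#'   (<= 0.005).
#' @param report Covariate names the "publication" reports; defaults to
#'   all.
#' @param seed Optional seed for the jitter.
#' @return A list with elements `curve`, `risk`, `baseline`.
#' @export
render_comparator <- function(data, curve_points = 120, risk_interval = 6,
                              jitter = 0, report = NULL, seed = NULL) {
  stopifnot(curve_points >= 10, jitter <= 0.005)
  if (!is.null(seed)) set.seed(seed)
  km <- km_estimate(data)
  horizon <- ipd_horizon(data)
  # a digitizer clicks where the published curve visibly steps: use the KM
  # event times, evenly thinned to the point budget
  steps <- km$time[km$n_event > 0]
  if (length(steps) > curve_points - 2) {
    steps <- steps[round(seq(1, length(steps), length.out = curve_points - 2))]
  }
  t_grid <- sort(unique(c(0, steps, horizon)))
  s_grid <- step_survival_at(km, t_grid + 1e-9)
  if (jitter > 0) {
    s_grid <- s_grid + runif(length(s_grid), -jitter, jitter)
    s_grid <- pmin(pmax(s_grid, 0), 1)
  }
  curve <- digitized_curve(t_grid, s_grid)
  r_times <- seq(0, horizon, by = risk_interval)
  n_risk <- vapply(r_times, function(tt) sum(data$time >= tt), numeric(1))
  risk <- risk_table(r_times, n_risk, total_events = sum(data$event))
  covs <- if (is.null(report)) ipd_covariates(data) else report
  cont <- .continuous_covariates(data, covs)
  vals <- vapply(covs, function(cv) {
    if (cv %in% cont) median(data[[cv]]) else mean(data[[cv]])
  }, numeric(1))
  baseline <- aggregate_baseline(vals, trial_label = attr(data, "arm_label"),
                                 follow_up = horizon, continuous = cont)
  list(curve = curve, risk = risk, baseline = baseline)
}

# covariate vocabulary and index-arm marginals used by the published-trial-style
# scenario (advanced RCC first-line population)
.rcc_covariate_model <- function() {
  list(
    AGE = cov_normal(62, 9),
    FEMALE = cov_bernoulli(0.28),
    IMDC_FAVOURABLE = cov_bernoulli(0.31),
    MSKCC_FAVOURABLE = cov_bernoulli(0.29),
    PDL1_LT1 = cov_bernoulli(0.315),
    SITES_GE2 = cov_bernoulli(0.715),
    BONE_LESIONS = cov_bernoulli(0.22),
    LYMPH_LESIONS = cov_bernoulli(0.45),
    LIVER_LESIONS = cov_bernoulli(0.18),
    LUNG_LESIONS = cov_bernoulli(0.71)
  )
}

#' A complete published-trial-style STC scenario, entirely synthetic
#'
#' One index IPD arm (default n = 350, ten RCC-style baseline covariates)
#' plus four comparator bundles -- each a digitized curve, risk table and
#' aggregate baseline with a different reported-covariate subset -- so the
#' full pipeline (alignment, per-comparator refit, Guyot reconstruction,
#' estimation) can be run end to end. With `null_effect = TRUE` all
#' covariate effects and the between-arm difference are zero, giving a
#' known-truth null for coverage checks.
#'
#' @param seed Integer seed.
#' @param n Index-arm size.
#' @param n_comparator Comparator-arm size.
#' @param null_effect Zero out covariate and treatment effects.
#' @return A list: `index` (IPD), `comparators` (list of bundles with
#'   `label`, `ipd`, `curve`, `risk`, `baseline`), `truth` (generator
#'   settings).
#' @export
make_rcc_scenario <- function(seed = 1, n = 350, n_comparator = 400,
                                     null_effect = FALSE) {
  set.seed(seed)
  cov_model <- .rcc_covariate_model()
  beta <- if (null_effect) {
    setNames(numeric(4), c("AGE", "IMDC_FAVOURABLE", "SITES_GE2", "MSKCC_FAVOURABLE"))
  } else {
    c(AGE = 0.012, IMDC_FAVOURABLE = -0.45, SITES_GE2 = 0.30, MSKCC_FAVOURABLE = -0.25)
  }
  mu <- -0.012 * 62   # anchor the acceleration factor near 1 at the mean age
  index_pars <- list(shape = 1.25, scale = 42)
  comp_scale <- if (null_effect) 42 else 32   # comparator survival worse
  index <- generate_ipd(n, "weibull", index_pars, beta = beta,
                        covariates = cov_model, mu = mu,
                        censoring = c(admin = 60, rate = 0.008),
                        arm_label = "index")
  reported <- list(
    "CM214-like" = c("AGE", "FEMALE", "IMDC_FAVOURABLE", "PDL1_LT1", "SITES_GE2",
                     "BONE_LESIONS", "LYMPH_LESIONS", "LIVER_LESIONS", "LUNG_LESIONS"),
    "J-like" = c("AGE", "FEMALE", "IMDC_FAVOURABLE", "MSKCC_FAVOURABLE", "SITES_GE2"),
    "KN426-like" = c("AGE", "FEMALE", "IMDC_FAVOURABLE", "PDL1_LT1", "SITES_GE2",
                     "BONE_LESIONS", "LYMPH_LESIONS", "LUNG_LESIONS"),
    "9ER-like" = names(cov_model))
  horizons <- c(74, 47, 64, 53)
  comparators <- imap(reported, function(covs, label) {
    i <- match(label, names(reported))
    ipd <- generate_ipd(n_comparator, "weibull",
                        list(shape = 1.25, scale = comp_scale),
                        beta = beta, covariates = cov_model, mu = mu,
                        censoring = c(admin = horizons[i], rate = 0.008),
                        arm_label = label)
    c(list(label = label, ipd = ipd),
      render_comparator(ipd, curve_points = 120, risk_interval = 6,
                        report = covs))
  })
  list(index = index, comparators = comparators,
       truth = list(family = "weibull", index_params = index_pars,
                    comparator_scale = comp_scale, beta = beta, mu = mu,
                    null_effect = null_effect))
}
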