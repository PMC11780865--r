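#' Knot placement for Royston-Parmar spline models
#'
#' Boundary knots sit at the smallest and largest log uncensored event
#' times; `m` internal knots sit at equally spaced quantiles of the log
#' uncensored event times (m = 1: median; m = 2: 33.3/66.7th percentiles;
#' m = 3: quartiles) -- the Royston-Parmar convention.
#'
#' @param data An [as_ipd()] dataset.
#' @param m Number of internal knots (0--3).
#' @return A list of class `spline_basis` with elements `k_min`, `k_max`,
#'   `internal` and `m`.
#' @export
place_knots <- function(data, m) {
  stopifnot(m %in% 0:3)
  lt <- log(data$time[data$event == 1])
  if (length(unique(lt)) < m + 2) {
    abort(sprintf("need at least %d distinct uncensored event times for %d internal knot(s)",
                  m + 2, m), class = "stc_validation_error")
  }
  internal <- if (m > 0) {
    unname(quantile(lt, probs = seq_len(m) / (m + 1), type = 7))
  } else numeric()
  structure(list(k_min = min(lt), k_max = max(lt), internal = internal, m = m),
            class = "spline_basis")
}

.all_knots <- function(basis) c(basis$k_min, basis$internal, basis$k_max)

#' Restricted cubic spline basis in log time
#'
#' For internal knots k_j with boundary knots k_min < k_max,
#' `v_j(u) = (u - k_j)+^3 - theta_j (u - k_min)+^3 - (1 - theta_j) (u - k_max)+^3`
#' with `theta_j = (k_max - k_j) / (k_max - k_min)`. The basis is zero below
#' k_min and linear beyond both boundary knots, so extrapolated log-time
#' trends are linear.
#'
#' @param basis A [place_knots()] result, or a numeric vector of all knots
#'   (boundary plus internal, increasing) in log time.
#' @param u Log-time value(s).
#' @param deriv If `TRUE`, return d v_j / d u instead.
#' @return A matrix with `length(u)` rows and `m` columns (0 columns when
#'   there are no internal knots).
#' @export
basis_values <- function(basis, u, deriv = FALSE) {
  knots <- if (inherits(basis, "spline_basis")) .all_knots(basis) else sort(basis)
  k_min <- knots[1]; k_max <- knots[length(knots)]
  internal <- knots[-c(1, length(knots))]
  m <- length(internal)
  out <- matrix(0, nrow = length(u), ncol = m)
  if (m == 0) return(out)
  cube <- function(x) pmax(x, 0)^3
  dcube <- function(x) 3 * pmax(x, 0)^2
  f <- if (deriv) dcube else cube
  for (j in seq_len(m)) {
    th <- (k_max - internal[j]) / (k_max - k_min)
    out[, j] <- f(u - internal[j]) - th * f(u - k_min) - (1 - th) * f(u - k_max)
  }
  out
}

# s(u) = gamma0 + gamma1 u + sum gamma_{j+1} v_j(u), and its u-derivative
.spline_s <- function(gamma, knots, u, deriv = FALSE) {
  v <- basis_values(knots, u, deriv = deriv)
  if (deriv) {
    gamma[2] + if (ncol(v)) drop(v %*% gamma[-(1:2)]) else 0
  } else {
    gamma[1] + gamma[2] * u + (if (ncol(v)) drop(v %*% gamma[-(1:2)]) else 0)
  }
}

.spline_links <- c("hazard", "odds", "normal")

# invert the link: survival from eta
.link_survival <- function(link, eta) {
  switch(link,
    hazard = exp(-exp(eta)),
    odds   = 1 / (1 + exp(eta)),
    normal = pnorm(-eta),
    abort(sprintf("unknown spline link '%s'", link), class = "stc_link_error"))
}

# g(S): eta from survival
.link_eta <- function(link, s) {
  switch(link,
    hazard = log(-log(s)),
    odds   = log(1 / s - 1),
    normal = -qnorm(s),
    abort(sprintf("unknown spline link '%s'", link), class = "stc_link_error"))
}

#' Survival and hazard of a Royston-Parmar spline model
#'
#' The linear predictor `eta = s(log t, gamma) + X beta` is passed through
#' the inverse link: `exp(-exp(eta))` (log cumulative-hazard link, the
#' Weibull extension), `1 / (1 + exp(eta))` (log cumulative-odds link, the
#' log-logistic extension) or `pnorm(-eta)` (inverse-normal link, the
#' log-normal extension). The hazard follows analytically:
#' `h(t) = w(eta) * s'(u) / t` with `w` the link-specific factor
#' (`exp(eta)`, `exp(eta) S`, or `dnorm(eta) / S`).
#'
#' @inheritParams aft_survival
#' @export
spline_survival <- function(model, newdata = NULL, t) {
  stopifnot(model$family == "spline", all(t >= 0))
  lp <- linear_predictor(model, newdata)
  out <- numeric(length(t))
  pos <- t > 0
  eta <- .spline_s(model$gamma, model$knots, log(t[pos])) + lp
  out[pos] <- .link_survival(model$link, eta)
  out[!pos] <- 1
  out
}

#' @rdname spline_survival
#' @export
spline_hazard <- function(model, newdata = NULL, t) {
  stopifnot(model$family == "spline")
  if (any(t <= 0)) abort("hazard requires t > 0", class = "stc_validation_error")
  lp <- linear_predictor(model, newdata)
  u <- log(t)
  eta <- .spline_s(model$gamma, model$knots, u) + lp
  ds <- .spline_s(model$gamma, model$knots, u, deriv = TRUE)
  w <- switch(model$link,
    hazard = exp(eta),
    odds   = exp(eta) / (1 + exp(eta)),
    normal = dnorm(eta) / pnorm(-eta),
    abort(sprintf("unknown spline link '%s'", model$link), class = "stc_link_error"))
  w * ds / t
}

# starting values for flexsurvspline from the nested m = 0 parametric
# analogue (Weibull / log-logistic / log-normal), knot coefficients zero
.spline_inits <- function(data, link, m, n_cov) {
  nested <- switch(link, hazard = "weibull", odds = "loglogistic", normal = "lognormal")
  f <- tryCatch(fit_parametric(data, nested), error = function(e) NULL)
  g01 <- if (is.null(f) || !f$converged) c(-3, 1) else {
    p <- f$baseline
    switch(link,
      hazard = c(-p[["shape"]] * log(p[["scale"]]), p[["shape"]]),
      odds   = c(-p[["shape"]] * log(p[["scale"]]), p[["shape"]]),
      normal = c(-p[["meanlog"]] / p[["sdlog"]], 1 / p[["sdlog"]]))
  }
  c(g01, rep(0, m), rep(0, n_cov))
}

#' Fit a Royston-Parmar flexible parametric survival model
#'
#' Maximum likelihood under right censoring for a restricted cubic spline
#' in log time with `m` internal knots (placed by [place_knots()]) under
#' the hazard, odds or normal link; covariates enter on the intercept
#' (gamma0) only. Fits whose cumulative transform s(u) is non-monotone over
#' the observed time range (an invalid survival function) are flagged
#' `converged = FALSE`, mirroring the convergence filter used in model
#' selection.
#'
#' @inheritParams fit_parametric
#' @param m Number of internal knots (0--3).
#' @param link `"hazard"`, `"odds"` or `"normal"`.
#' @export
fit_spline <- function(data, m, link = c("hazard", "odds", "normal"),
                       covariates = character()) {
  link <- match.arg(link)
  stopifnot(inherits(data, "stc_ipd"))
  if (!all(covariates %in% ipd_covariates(data))) {
    abort("covariates must be a subset of the dataset's covariates",
          class = "stc_covariate_error")
  }
  if (sum(data$event) < 1) {
    abort("all subjects are censored; cannot fit a survival model",
          class = "stc_validation_error")
  }
  basis <- place_knots(data, m)
  knots <- .all_knots(basis)
  cen <- .centering_map(data, covariates)
  d <- as.data.frame(data)
  for (cv in covariates) d[[cv]] <- d[[cv]] - cen[cv]
  fml <- if (length(covariates)) {
    stats::as.formula(paste("survival::Surv(time, event) ~",
                            paste(sprintf("`%s`", covariates), collapse = " + ")))
  } else survival::Surv(time, event) ~ 1
  fit_fun <- function(inits) {
    if (is.null(inits)) {
      flexsurv::flexsurvspline(fml, data = d, knots = basis$internal,
                               bknots = c(basis$k_min, basis$k_max),
                               scale = link)
    } else {
      flexsurv::flexsurvspline(fml, data = d, knots = basis$internal,
                               bknots = c(basis$k_min, basis$k_max),
                               scale = link, inits = inits)
    }
  }
  f <- tryCatch(suppressWarnings(fit_fun(NULL)), error = function(e) NULL)
  if (is.null(f) || !is.finite(f$loglik) || !isTRUE(f$opt$convergence == 0)) {
    f2 <- tryCatch(
      suppressWarnings(fit_fun(.spline_inits(data, link, m, length(covariates)))),
      error = function(e) NULL)
    if (!is.null(f2) && is.finite(f2$loglik) &&
        (is.null(f) || !is.finite(f$loglik) || f2$loglik > f$loglik)) {
      f <- f2
    }
  }
  fail <- stc_model("spline", link = link, knots = knots, converged = FALSE,
                    beta = setNames(rep(NA_real_, length(covariates)), covariates),
                    centering = cen, n = nrow(d), n_event = sum(d$event),
                    arm_label = attr(data, "arm_label"))
  if (is.null(f) || !is.finite(f$loglik)) return(fail)
  est <- setNames(f$res[, "est"], rownames(f$res))
  gamma <- unname(est[grep("^gamma", names(est))])
  beta <- if (length(covariates)) est[covariates] else numeric()
  names(beta) <- covariates
  # validity: s(u) must be non-decreasing over (and slightly beyond) the
  # observed log-time range for S(t) to be a survival function
  ugrid <- seq(log(min(data$time)) - 1, log(max(data$time)) + 1, length.out = 400)
  mono <- min(.spline_s(gamma, knots, ugrid, deriv = TRUE)) >= -1e-8
  conv <- isTRUE(f$opt$convergence == 0) && mono
  mod <- stc_model("spline", link = link, knots = knots, gamma = gamma,
                   beta = beta, mu = 0, centering = cen,
                   loglik = f$loglik, n_params = f$npars, aic = f$AIC,
                   vcov = f$cov, converged = conv,
                   n = nrow(d), n_event = sum(d$event),
                   arm_label = attr(data, "arm_label"))
  if (length(covariates)) mod$beta_se <- unname(f$res[covariates, "se"])
  mod
}
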