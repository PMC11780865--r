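#' Kaplan-Meier estimate as a step-function tibble
#'
#' Product-limit estimator via [survival::survfit()]; ties at a time are
#' processed events-before-censorings (the standard convention). The
#' returned table has one row per distinct observed time with the numbers
#' at risk, events, censorings, the survival estimate after that time and
#' its Greenwood standard error.
#'
#' @param data An [as_ipd()] dataset (covariates ignored).
#' @return A tibble of class `km_curve` with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, `std_err`.
#' @export
km_estimate <- function(data) {
  stopifnot(nrow(data) >= 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = as.data.frame(data), conf.type = "none")
  structure(tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                   n_censor = sf$n.censor, survival = sf$surv,
                   std_err = sf$surv * sf$std.err),
            n = nrow(data),
            class = c("km_curve", "tbl_df", "tbl", "data.frame"))
}

# evaluate a right-continuous step survival function (S = 1 before the
# first tabulated time) at arbitrary times
step_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$time)
  c(1, curve$survival)[idx + 1]
}

#' Restricted mean survival time of a step (KM-type) survival curve
#'
#' Exact area under the right-continuous step function from 0 to `tau`.
#' If `tau` exceeds the last tabulated time the curve is extended flat at
#' its last value, with a warning -- estimands in this package truncate at
#' the shorter trial horizon, so that path is exceptional.
#'
#' @param curve A [km_estimate()] result, [digitized_curve()], or any data
#'   frame with `time` and `survival` columns describing a step function.
#' @param tau Truncation time in months (> 0).
#' @return RMST in months.
#' @export
km_rmst <- function(curve, tau) {
  if (!is.numeric(tau) || tau <= 0) {
    abort("tau must be positive", class = "stc_validation_error")
  }
  tt <- curve$time
  ss <- curve$survival
  if (tau > max(tt)) {
    warn(sprintf("tau = %.3g beyond last observed time %.3g; curve extended flat",
                 tau, max(tt)))
  }
  keep <- tt < tau
  knots <- c(0, tt[keep], tau)
  heights <- c(1, ss[keep])              # S on [knots[i], knots[i+1])
  sum(heights * diff(knots))
}

#' Reconstruct pseudo individual patient data from a digitized KM curve
#'
#' The iterative Guyot algorithm: within each numbers-at-risk interval,
#' censorings are assumed uniformly spread and their count is adjusted
#' until the implied number at risk at the start of the next interval
#' matches the published one; event counts at each digitized coordinate
#' then follow from the survival drops. If the trial's total event count is
#' supplied the final interval is calibrated so the reconstruction matches
#' it exactly. Ties resolve events before censorings.
#'
#' @param curve A [digitized_curve()].
#' @param risk A [risk_table()] spanning the curve's time range.
#' @param total_events Total event count; defaults to the risk table's
#'   `total_events` attribute.
#' @param arm_label Label for the reconstructed arm.
#' @return An [as_ipd()] dataset of (time, event) pairs with no covariates.
#' @export
guyot_reconstruct <- function(curve, risk, total_events = NULL,
                              arm_label = "reconstructed") {
  if (is.null(total_events)) total_events <- attr(risk, "total_events")
  t_s <- curve$time; s <- curve$survival
  t_risk <- risk$time; n_risk <- as.numeric(risk$n_risk)
  n_int <- length(t_risk)
  K <- length(t_s)
  if (min(t_s) < min(t_risk)) {
    abort("risk table must span the digitized curve", class = "stc_validation_error")
  }
  # click-index range of each risk interval
  lower <- vapply(seq_len(n_int), function(i) {
    w <- which(t_s >= t_risk[i]); if (length(w)) min(w) else K + 1L
  }, numeric(1))
  upper <- c(vapply(seq_len(n_int - 1), function(i) {
    w <- which(t_s < t_risk[i + 1]); if (length(w)) max(w) else 0L
  }, numeric(1)), K)
  # drop risk intervals containing no digitized point
  keep <- lower <= upper
  if (!all(keep)) {
    t_risk <- t_risk[keep]; n_risk <- n_risk[keep]
    lower <- lower[keep]; upper <- upper[keep]
    n_int <- length(t_risk)
  }

  n_hat <- rep(NA_real_, K + 1); n_hat[1] <- n_risk[1]
  km_hat <- rep(1, K)
  d <- rep(0, K); cen <- rep(0, K); frac <- rep(0, K)
  n_censor <- rep(0, n_int)
  last_i <- rep(1L, n_int)

  run_interval <- function(i, n_censor_i) {
    # spread censorings uniformly over the interval, bin them by click,
    # then walk the clicks recomputing events from the survival drops
    lo <- lower[i]; up <- upper[i]
    t_end <- if (i < n_int) t_s[lower[i + 1]] else t_s[K]
    cen[lo:up] <<- 0
    if (n_censor_i > 0 && t_end > t_s[lo]) {
      ct <- t_s[lo] + seq_len(n_censor_i) * (t_end - t_s[lo]) / (n_censor_i + 1)
      cen[lo:up] <<- tabulate(findInterval(ct, t_s[lo:up]), nbins = up - lo + 1)
    }
    n_hat[lo] <<- n_risk[i]
    last <- last_i[i]
    for (k in lo:up) {
      if (i == 1 && k == lo) {
        d[k] <<- 0; km_hat[k] <<- 1; frac[k] <<- 0
      } else {
        frac[k] <<- if (n_hat[k] > 0 && km_hat[last] > 0) {
          n_hat[k] * (1 - s[k] / km_hat[last])
        } else 0
        d[k] <<- max(min(round(frac[k]), n_hat[k]), 0)
        km_hat[k] <<- if (n_hat[k] > 0) km_hat[last] * (1 - d[k] / n_hat[k]) else km_hat[last]
      }
      n_hat[k + 1] <<- max(n_hat[k] - d[k] - cen[k], 0)
      if (d[k] != 0) last <- k
    }
    if (i == n_int && n_hat[K + 1] > 0) {
      # subjects still at risk at the end of the curve are administratively
      # censored at the last digitized time
      cen[K] <<- cen[K] + n_hat[K + 1]
      n_hat[K + 1] <<- 0
    }
    last
  }

  if (n_int > 1) {
    for (i in seq_len(n_int - 1)) {
      n_censor[i] <- if (s[lower[i]] > 0) {
        round(n_risk[i] * s[lower[i + 1]] / s[lower[i]] - n_risk[i + 1])
      } else 0
      guard <- 0
      repeat {
        n_censor[i] <- max(n_censor[i], 0)
        last <- run_interval(i, n_censor[i])
        gap <- n_hat[lower[i + 1]] - n_risk[i + 1]
        guard <- guard + 1
        if (gap == 0 || (gap < 0 && n_censor[i] == 0) || guard > 500) break
        n_censor[i] <- n_censor[i] + gap
      }
      if (n_hat[lower[i + 1]] < n_risk[i + 1]) n_risk[i + 1] <- n_hat[lower[i + 1]]
      last_i[i + 1] <- last
    }
  }

  # final interval: assume censoring continues at the earlier per-person-time
  # rate (the risk set is far smaller by now, so a span-proportional guess
  # would overstate it)
  i <- n_int
  span_last <- t_s[upper[i]] - t_s[lower[i]]
  n_censor[i] <- if (i > 1) {
    spans <- t_s[lower[-1]] - t_s[lower[-n_int]]
    person_time <- sum(n_risk[-n_int] * spans)
    rate <- if (person_time > 0) sum(n_censor[seq_len(i - 1)]) / person_time else 0
    min(round(rate * n_risk[i] * span_last), n_risk[i])
  } else 0
  run_interval(i, max(n_censor[i], 0))

  if (!is.null(total_events)) {
    # calibrate to the reported total event count by swapping events and
    # censorings at the clicks where rounding was most marginal; a swap at
    # a click leaves every number-at-risk untouched
    diff_ev <- total_events - sum(d)
    guard <- 0
    while (diff_ev != 0 && guard < 4 * K) {
      slack <- frac - d
      if (diff_ev > 0) {
        cand <- which(cen > 0)
        if (length(cand) == 0) break
        k <- cand[which.max(slack[cand])]
        cen[k] <- cen[k] - 1; d[k] <- d[k] + 1; diff_ev <- diff_ev - 1
      } else {
        cand <- which(d > 0)
        if (length(cand) == 0) break
        k <- cand[which.min(slack[cand])]
        d[k] <- d[k] - 1; cen[k] <- cen[k] + 1; diff_ev <- diff_ev + 1
      }
      guard <- guard + 1
    }
  }

  ev_times <- rep(t_s, d)
  ct_all <- unlist(lapply(seq_len(K), function(k) {
    if (cen[k] == 0) return(numeric(0))
    t_next <- if (k < K) t_s[k + 1] else t_s[K] + 1e-6
    t_s[k] + seq_len(cen[k]) * (t_next - t_s[k]) / (cen[k] + 1)
  }))
  times <- c(ev_times, ct_all)
  events <- c(rep(1L, length(ev_times)), rep(0L, length(ct_all)))
  eps <- min(t_s[t_s > 0], 1) / 2
  times[times <= 0] <- eps  # log-time models reject t = 0
  out <- tibble(time = times, event = events)
  out <- out[order(out$time, -out$event), ]
  as_ipd(out, arm_label = arm_label)
}

#' Kernel-smoothed hazard from Kaplan-Meier data
#'
#' Epanechnikov-kernel smoothing of the Nelson-Aalen increments:
#' `h(t) = sum_i K_b(t - t_i) d_i / n_i`, with boundary correction by
#' renormalising the kernel mass inside the observed window (0, t_max).
#' The automatic bandwidth is (t_last - t_first_event) / 8.
#'
#' @param data An [as_ipd()] dataset with at least 5 events.
#' @param grid Evaluation times; defaults to 101 points over follow-up.
#'   Points beyond follow-up are an error.
#' @param bandwidth Bandwidth in months, or `"auto"`.
#' @return A tibble of class `kernel_hazard` with columns `time`, `hazard`
#'   and attributes `bandwidth`, `kernel`, `events`, `t_max`.
#' @export
kernel_hazard <- function(data, grid = NULL, bandwidth = "auto") {
  stopifnot(inherits(data, "stc_ipd"))
  if (sum(data$event) < 5) {
    abort("kernel hazard estimation needs at least 5 events",
          class = "stc_validation_error")
  }
  km <- km_estimate(data)
  ev <- km[km$n_event > 0, ]
  t_max <- max(data$time)
  if (identical(bandwidth, "auto")) {
    bandwidth <- (t_max - min(ev$time)) / 8
  }
  stopifnot(is.numeric(bandwidth), bandwidth > 0)
  if (is.null(grid)) grid <- seq(0, t_max, length.out = 101)
  if (any(grid > t_max + 1e-9) || any(grid < 0)) {
    abort("grid points must lie within observed follow-up",
          class = "stc_validation_error")
  }
  haz <- .eval_kernel_hazard(grid, ev$time, ev$n_event / ev$n_risk, bandwidth, t_max)
  structure(tibble(time = grid, hazard = haz),
            bandwidth = bandwidth, kernel = "epanechnikov",
            events = tibble(time = ev$time, increment = ev$n_event / ev$n_risk),
            t_max = t_max,
            class = c("kernel_hazard", "tbl_df", "tbl", "data.frame"))
}

# integral of the standardized Epanechnikov kernel up to v
.epan_cdf <- function(v) {
  v <- pmin(pmax(v, -1), 1)
  0.5 + 0.75 * v - 0.25 * v^3
}

.eval_kernel_hazard <- function(t, ev_time, increment, b, t_max) {
  vapply(t, function(ti) {
    v <- (ti - ev_time) / b
    w <- ifelse(abs(v) < 1, 0.75 * (1 - v^2) / b, 0)
    # cut-and-normalise boundary correction: kernel mass inside [0, t_max]
    mass <- .epan_cdf((t_max - ti) / b) - .epan_cdf((0 - ti) / b)
    sum(w * increment) / max(mass, 1e-12)
  }, numeric(1))
}

#' Evaluate a kernel hazard estimate at arbitrary times
#'
#' @param kh A [kernel_hazard()] result.
#' @param t Times within observed follow-up.
#' @export
hazard_at <- function(kh, t) {
  t_max <- attr(kh, "t_max")
  if (any(t > t_max + 1e-9) || any(t < 0)) {
    abort("time beyond observed follow-up", class = "stc_validation_error")
  }
  ev <- attr(kh, "events")
  .eval_kernel_hazard(t, ev$time, ev$increment, attr(kh, "bandwidth"), t_max)
}
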