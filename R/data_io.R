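#' Build a validated individual-patient-data (IPD) survival dataset
#'
#' Validates and tags a subject-level data frame for use throughout the
#' package: one row per subject, a strictly positive follow-up time in
#' months, a 0/1 event indicator, and zero or more numeric baseline
#' covariates. Missing covariate values are rejected at this boundary so
#' every downstream fit sees complete data.
#'
#' @param data A data frame with one row per subject.
#' @param time,event Names of the time and event columns. Times must be
#'   strictly positive (time 0 is rejected, not shifted: log-time models are
#'   undefined there and silent shifting hides data errors). Events must be
#'   coded 0/1.
#' @param covariates Character vector of covariate column names. Defaults to
#'   every column other than `id`, time and event. Binary covariates must be
#'   coded 0/1; continuous covariates are passed through unscaled (centering
#'   happens inside model fitting).
#' @param id Optional name of a subject-identifier column; generated if
#'   absent.
#' @param arm_label Label for the treatment arm.
#' @return A tibble of class `stc_ipd` with columns `id`, `time`, `event`
#'   and the covariates, carrying `covariates` and `arm_label` attributes.
#' @export
as_ipd <- function(data, time = "time", event = "event", covariates = NULL,
                   id = NULL, arm_label = "index") {
  stopifnot(is.data.frame(data))
  for (col in c(time, event)) {
    if (!col %in% names(data)) {
      abort(sprintf("required column '%s' not found", col), class = "stc_schema_error")
    }
  }
  t <- as.numeric(data[[time]])
  e <- data[[event]]
  bad_t <- which(!is.finite(t) | t <= 0)
  if (length(bad_t) > 0) {
    abort(sprintf("non-positive or missing time in row %s", bad_t[1]),
          class = "stc_validation_error")
  }
  bad_e <- which(!(e %in% c(0, 1)))
  if (length(bad_e) > 0) {
    abort(sprintf("event indicator not in {0,1} in row %s", bad_e[1]),
          class = "stc_validation_error")
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c("id", id, time, event))
  }
  for (cv in covariates) {
    if (!cv %in% names(data)) {
      abort(sprintf("covariate column '%s' not found", cv), class = "stc_schema_error")
    }
    v <- data[[cv]]
    if (!is.numeric(v)) {
      abort(sprintf("covariate '%s' is not numeric", cv), class = "stc_validation_error")
    }
    if (anyNA(v)) {
      abort(sprintf("missing value in covariate '%s'", cv),
            class = "stc_validation_error")
    }
  }
  ids <- if (!is.null(id)) as.character(data[[id]]) else sprintf("s%04d", seq_len(nrow(data)))
  out <- tibble(id = ids, time = t, event = as.integer(e))
  for (cv in covariates) out[[cv]] <- as.numeric(data[[cv]])
  structure(out,
            covariates = covariates,
            arm_label = arm_label,
            class = c("stc_ipd", class(out)))
}

#' @rdname as_ipd
#' @param x An `stc_ipd` object.
#' @export
ipd_covariates <- function(x) attr(x, "covariates") %||% character()

#' @rdname as_ipd
#' @export
ipd_horizon <- function(x) max(x$time)

#' Read / write IPD as CSV
#'
#' Comma-separated, header row required, UTF-8. `write_ipd()` then
#' `read_ipd()` reproduces times, events and covariates exactly.
#'
#' @param path File path.
#' @inheritParams as_ipd
#' @return `read_ipd()` returns an [as_ipd()] dataset.
#' @export
read_ipd <- function(path, time = "time", event = "event", covariates = NULL,
                     id = NULL, arm_label = "index") {
  df <- utils::read.csv(path)
  if (is.null(id) && "id" %in% names(df)) id <- "id"
  as_ipd(df, time = time, event = event, covariates = covariates,
         id = id, arm_label = arm_label)
}

#' @rdname read_ipd
#' @param x Dataset to write.
#' @export
write_ipd <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Digitized Kaplan-Meier curve
#'
#' Coordinates read off a published KM plot: (time, survival) pairs with
#' strictly increasing times. A (0, 1) anchor is prepended if absent and
#' survival values are clamped to the running minimum (digitization noise
#' can make them locally increase); the number of clamped points is kept as
#' the `n_clamped` attribute. Survival outside [0, 1] by more than 0.005 is
#' an error.
#'
#' @param time,survival Numeric vectors of equal length.
#' @return A tibble of class `digitized_curve`.
#' @export
digitized_curve <- function(time, survival) {
  stopifnot(length(time) == length(survival))
  if (any(!is.finite(time)) || any(!is.finite(survival))) {
    abort("non-finite value in digitized curve", class = "stc_validation_error")
  }
  if (any(diff(time) <= 0)) {
    abort("digitized times must be strictly increasing", class = "stc_validation_error")
  }
  if (any(time < 0)) abort("negative time in digitized curve", class = "stc_validation_error")
  if (any(survival > 1 + 0.005) || any(survival < -0.005)) {
    abort("survival outside [0,1] beyond tolerance 0.005", class = "stc_validation_error")
  }
  survival <- pmin(pmax(survival, 0), 1)
  n_clamped <- 0L
  if (length(time) == 0 || time[1] > 0) {
    time <- c(0, time)
    survival <- c(1, survival)
  } else {
    # a point at t = 0 must be the (0, 1) anchor
    if (abs(survival[1] - 1) > 0.005) {
      abort("curve at time 0 must have survival 1", class = "stc_validation_error")
    }
    survival[1] <- 1
  }
  runmin <- cummin(survival)
  n_clamped <- sum(survival > runmin)
  structure(tibble(time = time, survival = runmin),
            n_clamped = as.integer(n_clamped),
            class = c("digitized_curve", "tbl_df", "tbl", "data.frame"))
}

#' @rdname digitized_curve
#' @param path CSV file with header columns `time,survival`.
#' @export
read_digitized_curve <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time", "survival") %in% names(df))) {
    abort("digitized curve file needs 'time' and 'survival' columns",
          class = "stc_schema_error")
  }
  dc <- digitized_curve(df$time, df$survival)
  if (attr(dc, "n_clamped") > 0) {
    inform(sprintf("%d survival value(s) clamped to running minimum",
                   attr(dc, "n_clamped")))
  }
  dc
}

#' @rdname digitized_curve
#' @param x Curve to write.
#' @export
write_digitized_curve <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Numbers-at-risk table accompanying a digitized KM curve
#'
#' @param time Interval start times (months), beginning at 0.
#' @param n_risk Non-negative, non-increasing integer counts at risk.
#' @param total_events Optional total event count reported by the trial;
#'   used by [guyot_reconstruct()] to calibrate the reconstruction.
#' @return A tibble of class `risk_table` with a `total_events` attribute.
#' @export
risk_table <- function(time, n_risk, total_events = NULL) {
  stopifnot(length(time) == length(n_risk))
  if (time[1] != 0) abort("risk table must start at time 0", class = "stc_validation_error")
  if (any(diff(time) <= 0)) abort("risk-table times must increase", class = "stc_validation_error")
  if (any(n_risk < 0) || any(n_risk != round(n_risk))) {
    abort("numbers at risk must be non-negative integers", class = "stc_validation_error")
  }
  if (any(diff(n_risk) > 0)) {
    abort("numbers at risk must be non-increasing", class = "stc_validation_error")
  }
  if (!is.null(total_events)) {
    stopifnot(total_events >= 0, total_events == round(total_events))
  }
  structure(tibble(time = as.numeric(time), n_risk = as.integer(n_risk)),
            total_events = total_events,
            class = c("risk_table", "tbl_df", "tbl", "data.frame"))
}

#' @rdname risk_table
#' @param path CSV file with header columns `time,n_risk`.
#' @export
read_risk_table <- function(path, total_events = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time", "n_risk") %in% names(df))) {
    abort("risk table file needs 'time' and 'n_risk' columns", class = "stc_schema_error")
  }
  risk_table(df$time, df$n_risk, total_events = total_events)
}

#' @rdname risk_table
#' @param x Table to write.
#' @export
write_risk_table <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  invisible(path)
}

#' Aggregate baseline characteristics of a comparator trial
#'
#' The mean-covariate vector at which the index model is evaluated: reported
#' proportions for binary covariates and a central (median or mean) value
#' for continuous ones, together with the trial follow-up horizon.
#' Covariates a trial did not report are simply absent (not zero); the
#' covariate-alignment step drops them from the regression before
#' prediction.
#'
#' @param values Named numeric vector or list of reported covariate values.
#' @param trial_label Trial name.
#' @param follow_up Follow-up horizon in months (> 0).
#' @param continuous Names of continuous covariates in `values` (exempt from
#'   the \[0, 1\] proportion check).
#' @return A list of class `aggregate_baseline`.
#' @export
aggregate_baseline <- function(values, trial_label = "comparator", follow_up,
                               continuous = character()) {
  values <- unlist(values)
  stopifnot(is.numeric(values) || length(values) == 0)
  if (is.null(names(values)) && length(values) > 0) {
    abort("baseline values must be named by covariate", class = "stc_schema_error")
  }
  stopifnot(is.numeric(follow_up), follow_up > 0)
  prop <- setdiff(names(values), continuous)
  bad <- prop[values[prop] < 0 | values[prop] > 1]
  if (length(bad) > 0) {
    abort(sprintf("proportion outside [0,1] for covariate '%s'", bad[1]),
          class = "stc_validation_error")
  }
  structure(list(values = values, trial_label = trial_label,
                 follow_up = follow_up, continuous = continuous),
            class = "aggregate_baseline")
}

#' @rdname aggregate_baseline
#' @param path JSON (or YAML, by extension) file with fields `trial_label`,
#'   `follow_up`, `values` and optionally `continuous`.
#' @export
read_aggregate_baseline <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("the 'yaml' package is needed to read YAML baselines")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  aggregate_baseline(values = unlist(obj$values),
                     trial_label = obj$trial_label %||% "comparator",
                     follow_up = obj$follow_up,
                     continuous = obj$continuous %||% character())
}

#' @rdname aggregate_baseline
#' @param x Baseline to write.
#' @export
write_aggregate_baseline <- function(x, path) {
  jsonlite::write_json(
    list(trial_label = x$trial_label, follow_up = x$follow_up,
         values = as.list(x$values), continuous = x$continuous),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.aggregate_baseline <- function(x, ...) {
  cat("Aggregate baseline:", x$trial_label,
      sprintf("(follow-up %.1f months)\n", x$follow_up))
  if (length(x$values)) {
    print(tibble(covariate = names(x$values), value = unname(x$values)))
  } else {
    cat("  (no reported covariates)\n")
  }
  invisible(x)
}
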