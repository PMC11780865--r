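# Small fixtures shared across test files. Everything is built in code;
# nothing is read from disk except what a test itself writes to tempdir().

ipd_from <- function(time, event, ...) {
  df <- data.frame(time = time, event = event, ...)
  covs <- setdiff(names(df), c("time", "event"))
  as_ipd(df, covariates = covs)
}

# a moderately censored Weibull arm used by several fitting tests
weibull_arm <- function(n = 300, seed = 1, beta = NULL, scale = 20) {
  covs <- if (is.null(beta)) list() else list(x = cov_bernoulli(0.5))
  generate_ipd(n, "weibull", list(shape = 1.3, scale = scale),
               beta = beta %||% numeric(), covariates = covs,
               censoring = c(admin = 48, rate = 0.02), seed = seed)
}

empty_baseline <- function(follow_up = 24, label = "comparator") {
  aggregate_baseline(setNames(numeric(0), character(0)),
                     trial_label = label, follow_up = follow_up)
}

`%||%` <- rlang::`%||%`
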