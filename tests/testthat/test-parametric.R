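test_that("linear predictor is exact and strict about covariates", {
  m0 <- stc_model("exponential", baseline = c(rate = 1), mu = 0.7)
  expect_equal(linear_predictor(m0, c(ignored = 99)), 0.7)

  m <- stc_model("exponential", baseline = c(rate = 1), beta = c(x = log(2)))
  expect_equal(linear_predictor(m, c(x = 1)), log(2))
  expect_error(linear_predictor(m, c(y = 1)), "'x'")

  m2 <- stc_model("exponential", baseline = c(rate = 1),
                  beta = c(a = 1, b = -1), mu = 0.5)
  expect_equal(linear_predictor(m2, c(a = 2, b = 2)), 0.5)
})

test_that("AFT survival and hazard match closed forms", {
  m <- stc_model("exponential", baseline = c(rate = 0.5), beta = c(x = log(2)))
  expect_equal(aft_survival(m, c(x = 1), 1), exp(-1))
  expect_equal(aft_survival(m, c(x = 1), 0), 1)
  # theta = 1 reproduces the baseline curve
  expect_equal(aft_survival(m, c(x = 0), c(1, 3, 7)), exp(-0.5 * c(1, 3, 7)))
  # exponential hazard is constant theta * lambda
  expect_equal(aft_hazard(m, c(x = 1), c(1, 5, 20)), rep(1, 3))

  mw <- stc_model("weibull", baseline = c(shape = 2, scale = 1))
  expect_equal(aft_hazard(mw, NULL, 1), 2)
  expect_error(aft_hazard(mw, NULL, 0), "t > 0")

  mg <- stc_model("gompertz", baseline = c(shape = 0.1, rate = 0.2))
  expect_error(aft_survival(mg, NULL, 1), "not an AFT family")
})

test_that("hazard equals -d/dt log survival for every family", {
  pars <- list(exponential = c(rate = 0.3),
               weibull = c(shape = 1.4, scale = 10),
               gamma = c(shape = 2, rate = 0.25),
               loglogistic = c(shape = 1.8, scale = 12),
               lognormal = c(meanlog = 2.2, sdlog = 0.7),
               genf = c(mu = 2.2, sigma = 0.7, Q = 0.5, P = 0.3),
               gompertz = c(shape = 0.05, rate = 0.04))
  tt <- c(2, 5, 11, 19)
  h <- 1e-5
  for (fam in names(pars)) {
    m <- stc_model(fam, baseline = pars[[fam]], beta = c(x = 0.3))
    X <- c(x = 1)
    num <- -(log(model_survival(m, X, tt + h)) -
               log(model_survival(m, X, tt - h))) / (2 * h)
    expect_equal(model_hazard(m, X, tt), num, tolerance = 1e-5,
                 label = paste(fam, "hazard"))
  }
})

test_that("exponential MLE has its closed form", {
  d <- ipd_from(time = 1:4, event = 1)
  f <- fit_parametric(d, "exponential")
  expect_equal(f$baseline[["rate"]], 0.4, tolerance = 1e-6)
  expect_equal(f$loglik, 4 * log(0.4) - 4, tolerance = 1e-8)
  expect_equal(f$aic, -2 * f$loglik + 2 * f$n_params)
  expect_true(f$converged)

  expect_error(fit_parametric(ipd_from(time = 1:3, event = 0), "exponential"),
               "censored")
})

test_that("doubling a covariate with beta = log(2) halves predicted median survival", {
  m <- stc_model("weibull", baseline = c(shape = 1.3, scale = 20),
                 beta = c(x = log(2)))
  median_at <- function(x) {
    uniroot(function(t) aft_survival(m, c(x = x), t) - 0.5, c(1e-6, 200))$root
  }
  expect_equal(median_at(2), median_at(1) / 2, tolerance = 1e-6)
})

test_that("S(t|X) always equals S0(t * exp(lp)) for AFT fits", {
  d <- weibull_arm(250, seed = 8, beta = c(x = 0.5))
  tt <- seq(0.5, 40, length.out = 50)
  for (fam in c("exponential", "weibull", "gamma", "loglogistic", "lognormal")) {
    f <- fit_parametric(d, fam, "x")
    theta <- exp(linear_predictor(f, c(x = 1)))
    direct <- aft_survival(f, c(x = 1), tt)
    via_theta <- stcsurv:::.baseline_survival(fam, tt * theta, f$baseline)
    expect_equal(direct, via_theta, tolerance = 1e-12, label = fam)
  }
})

test_that("likelihood is invariant to covariate centering", {
  set.seed(11)
  d <- generate_ipd(250, "weibull", list(shape = 1.3, scale = 22),
                    beta = c(age = 0.02),
                    covariates = list(age = cov_normal(60, 9)),
                    censoring = c(admin = 48, rate = 0.02))
  f <- fit_parametric(d, "weibull", "age")
  # same fit with the covariate pre-centered by hand (centering then a no-op)
  d2 <- d
  d2$age <- d$age - mean(d$age)
  f2 <- fit_parametric(as_ipd(as.data.frame(d2), covariates = "age"),
                       "weibull", "age")
  expect_equal(f$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f$beta[["age"]], f2$beta[["age"]], tolerance = 1e-4)
  # and predictions at the same absolute covariate value agree
  expect_equal(aft_survival(f, c(age = 65), c(6, 12, 24)),
               aft_survival(f2, c(age = 65 - mean(d$age)), c(6, 12, 24)),
               tolerance = 1e-4)
})

test_that("nested families order their likelihoods", {
  for (seed in c(3, 9)) {
    d <- weibull_arm(200, seed = seed)
    fe <- fit_parametric(d, "exponential")
    fw <- fit_parametric(d, "weibull")
    expect_gte(fw$loglik, fe$loglik - 1e-6)
  }
})

test_that("generalized F reduces to log-logistic and log-normal at its limits", {
  tt <- seq(0.5, 60, by = 0.5)
  mu <- 2.8; sigma <- 0.75
  s_genf_ln <- flexsurv::pgenf(tt, mu, sigma, Q = 0, P = 0, lower.tail = FALSE)
  expect_equal(s_genf_ln, plnorm(tt, mu, sigma, lower.tail = FALSE),
               tolerance = 1e-4)
  s_genf_ll <- flexsurv::pgenf(tt, mu, sigma, Q = 0, P = 1, lower.tail = FALSE)
  expect_equal(s_genf_ll,
               flexsurv::pllogis(tt, shape = sqrt(2) / sigma, scale = exp(mu),
                                 lower.tail = FALSE),
               tolerance = 1e-4)
})

test_that("Gompertz behaves as a proportional-hazards model", {
  m <- stc_model("gompertz", baseline = c(shape = 0.08, rate = 0.05),
                 beta = c(x = 0.6))
  tt <- c(2, 8, 15)
  h0 <- model_hazard(m, c(x = 0), tt)
  h1 <- model_hazard(m, c(x = 1), tt)
  expect_equal(h1 / h0, rep(exp(0.6), 3), tolerance = 1e-10)
  expect_equal(model_survival(m, c(x = 1), tt),
               model_survival(m, c(x = 0), tt)^exp(0.6), tolerance = 1e-10)
})

test_that("refitting the same data is bit-identical", {
  d <- weibull_arm(150, seed = 5)
  f1 <- fit_parametric(d, "weibull")
  f2 <- fit_parametric(d, "weibull")
  expect_identical(f1$baseline, f2$baseline)
  expect_identical(f1$loglik, f2$loglik)
})
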