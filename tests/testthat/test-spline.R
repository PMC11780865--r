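test_that("knots sit at quantiles of log uncensored event times", {
  d <- ipd_from(time = exp(0:2), event = 1)
  b <- place_knots(d, 1)
  expect_equal(b$k_min, 0)
  expect_equal(b$k_max, 2)
  expect_equal(b$internal, 1)

  b0 <- place_knots(d, 0)
  expect_length(b0$internal, 0)

  expect_error(place_knots(ipd_from(time = rep(5, 4), event = 1), 1),
               "distinct")
})

test_that("restricted cubic basis matches its formula and tail behaviour", {
  # hand evaluation: k = (0, 0.5, 1), u = 1 -> theta = 0.5,
  # v = 0.125 - 0.5*1 - 0 = -0.375
  expect_equal(drop(basis_values(c(0, 0.5, 1), 1)), -0.375)

  # zero below the lower boundary knot
  expect_equal(drop(basis_values(c(0, 0.5, 1), c(-2, -0.1, 0))), rep(0, 3))

  # s(u) is linear beyond both boundary knots and C2 at the knots
  set.seed(6)
  knots <- sort(runif(4, -1, 3))
  gamma <- c(0.2, 1.1, rnorm(2, 0, 0.4))
  s <- function(u) stcsurv:::.spline_s(gamma, knots, u)
  h <- 1e-3
  d2 <- function(u) (s(u + h) - 2 * s(u) + s(u - h)) / h^2
  outside <- c(knots[1] - c(2, 1, 0.2), knots[4] + c(0.2, 1, 2))
  expect_true(all(abs(d2(outside)) < 1e-6))
  for (k in knots[2:3]) {
    expect_equal(d2(k - 1e-4), d2(k + 1e-4), tolerance = 1e-2)
  }
})

test_that("m = 0 spline survival inverts each link in closed form", {
  mh <- stc_model("spline", link = "hazard", gamma = c(0, 1), knots = c(-2, 3))
  expect_equal(spline_survival(mh, NULL, c(0.5, 1, 2)), exp(-c(0.5, 1, 2)))
  expect_equal(spline_survival(mh, NULL, 0), 1)
  expect_equal(spline_hazard(mh, NULL, c(0.5, 1, 4)), rep(1, 3))

  mo <- stc_model("spline", link = "odds", gamma = c(0, 1), knots = c(-2, 3))
  expect_equal(spline_survival(mo, NULL, 1), 0.5)
  expect_equal(spline_survival(mo, NULL, c(1, 3)), 1 / (1 + c(1, 3)))
  expect_equal(spline_hazard(mo, NULL, 1), 0.5)
  expect_equal(spline_hazard(mo, NULL, c(0.5, 2)), 1 / (1 + c(0.5, 2)))

  mn <- stc_model("spline", link = "normal", gamma = c(0, 1), knots = c(-2, 3))
  expect_equal(spline_survival(mn, NULL, 1), 0.5)
  expect_equal(spline_survival(mn, NULL, exp(1)), pnorm(-1))

  bad <- stc_model("spline", link = "hazard", gamma = c(0, 1), knots = c(-2, 3))
  bad$link <- "logit"
  expect_error(spline_survival(bad, NULL, 1), "unknown spline link")
})

test_that("spline hazard agrees with numerical differentiation of log survival", {
  set.seed(13)
  for (link in c("hazard", "odds", "normal")) {
    knots <- sort(c(-0.5, runif(2, 0.2, 2.3), 3))
    gamma <- c(-1.5, 1.2, rnorm(2, 0, 0.25))
    m <- stc_model("spline", link = link, gamma = gamma, knots = knots,
                   beta = c(x = 0.4))
    X <- c(x = 0.7)
    tt <- c(0.8, 2.5, 7, 15)
    h <- 1e-6
    num <- -(log(spline_survival(m, X, tt + h)) -
               log(spline_survival(m, X, tt - h))) / (2 * h)
    expect_equal(spline_hazard(m, X, tt), num, tolerance = 1e-4, label = link)
  }
})

test_that("m = 0 spline fits recover their nested parametric models", {
  d <- weibull_arm(300, seed = 3)
  pairs <- list(hazard = "weibull", odds = "loglogistic", normal = "lognormal")
  for (link in names(pairs)) {
    fs <- fit_spline(d, 0, link)
    fp <- fit_parametric(d, pairs[[link]])
    expect_equal(fs$loglik, fp$loglik, tolerance = 1e-4, label = link)
    tt <- seq(1, 40, length.out = 30)
    expect_equal(spline_survival(fs, NULL, tt), aft_survival(fp, NULL, tt),
                 tolerance = 1e-3, label = link)
  }
})

test_that("adding a knot never decreases the maximized log-likelihood", {
  d <- weibull_arm(250, seed = 17)
  for (link in c("hazard", "odds")) {
    lls <- vapply(0:2, function(m) fit_spline(d, m, link)$loglik, numeric(1))
    expect_true(all(diff(lls) >= -1e-3), label = link)
  }
})

test_that("converged spline fits yield monotone survival", {
  set.seed(23)
  for (i in 1:5) {
    d <- weibull_arm(200, seed = 100 + i)
    f <- fit_spline(d, sample(1:3, 1), sample(c("hazard", "odds", "normal"), 1))
    if (!f$converged) next
    tt <- seq(0.05, 48, length.out = 1000)
    s <- spline_survival(f, NULL, tt)
    expect_true(all(diff(s) <= 1e-10))
  }
})

test_that("covariates shift the spline curve only through the intercept", {
  set.seed(31)
  d <- generate_ipd(300, "weibull", list(shape = 1.3, scale = 25),
                    beta = c(x = 0.5), covariates = list(x = cov_bernoulli(0.5)),
                    censoring = c(admin = 48, rate = 0.02))
  f <- fit_spline(d, 1, "hazard", "x")
  # lp = 0 reproduces the no-covariate curve of the same coefficients
  f0 <- f; f0$beta <- numeric(); f0$covariates <- character()
  tt <- c(3, 9, 20)
  expect_equal(spline_survival(f, setNames(f$centering["x"], "x"), tt),
               spline_survival(f0, NULL, tt))
})
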