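test_that("product-limit estimator matches hand calculations", {
  k <- km_estimate(ipd_from(time = 1:3, event = 1))
  expect_equal(k$survival, c(2 / 3, 1 / 3, 0))

  # all censored: survival stays at 1
  k2 <- km_estimate(ipd_from(time = c(2, 5), event = 0))
  expect_true(all(k2$survival == 1))

  # 1+, 2, 3+, 4: risk sets 3 then 1
  k3 <- km_estimate(ipd_from(time = 1:4, event = c(0, 1, 0, 1)))
  expect_equal(stcsurv:::step_survival_at(k3, 2), 2 / 3)
  expect_equal(stcsurv:::step_survival_at(k3, 4), 0)

  # no censoring: equals the empirical survival function
  set.seed(5)
  tt <- rexp(40, 0.1)
  k4 <- km_estimate(ipd_from(time = tt, event = 1))
  expect_equal(stcsurv:::step_survival_at(k4, sort(tt) + 1e-9),
               1 - seq_along(tt) / length(tt))
})

test_that("step RMST is exact rectangle area and monotone in tau", {
  curve <- tibble::tibble(time = c(2, 4), survival = c(0.5, 0))
  expect_equal(km_rmst(curve, 4), 3)
  expect_equal(km_rmst(curve, 2), 2)
  expect_error(km_rmst(curve, 0), "positive")
  expect_warning(r <- km_rmst(curve, 6), "extended flat")
  expect_equal(r, 3)

  # matches fine-grid quadrature of the same step function
  set.seed(9)
  k <- km_estimate(ipd_from(time = rexp(60, 0.1), event = rbinom(60, 1, 0.8)))
  tau <- max(k$time) * 0.9
  tg <- seq(0, tau, length.out = 2e5)
  quad <- mean(stcsurv:::step_survival_at(k, tg[-1] - diff(tg) / 2)) * tau
  expect_equal(km_rmst(k, tau), quad, tolerance = 1e-6)

  taus <- seq(1, tau, length.out = 20)
  expect_true(all(diff(vapply(taus, km_rmst, numeric(1), curve = k)) >= 0))
})

test_that("Guyot reconstruction round-trips a simulated arm", {
  set.seed(77)
  ipd <- generate_ipd(300, "exponential", list(rate = 0.03),
                      censoring = c(admin = 48, rate = 0.015))
  rc <- render_comparator(ipd, curve_points = 120, risk_interval = 6)
  rec <- guyot_reconstruct(rc$curve, rc$risk)
  tg <- seq(0.05, ipd_horizon(ipd) - 0.05, length.out = 500)
  err <- max(abs(stcsurv:::step_survival_at(km_estimate(ipd), tg) -
                   stcsurv:::step_survival_at(km_estimate(rec), tg)))
  expect_lt(err, 0.02)
  expect_equal(sum(rec$event), sum(ipd$event))
  expect_equal(nrow(rec), nrow(ipd))
})

test_that("flat curve with constant risk reconstructs zero events", {
  dc <- digitized_curve(c(0, 6, 12, 18, 24), rep(1, 5))
  rt <- risk_table(c(0, 12, 24), c(50, 50, 50))
  rec <- guyot_reconstruct(dc, rt)
  expect_equal(sum(rec$event), 0)
  expect_equal(nrow(rec), 50)
})

test_that("supplied total event count is honoured exactly", {
  set.seed(12)
  ipd <- generate_ipd(250, "weibull", list(shape = 1.2, scale = 30),
                      censoring = c(admin = 48, rate = 0.02))
  rc <- render_comparator(ipd, curve_points = 110, risk_interval = 6)
  rec <- guyot_reconstruct(rc$curve, rc$risk, total_events = 57)
  expect_equal(sum(rec$event), 57)
})

test_that("kernel hazard recovers a constant hazard away from the boundaries", {
  big <- generate_ipd(5000, "exponential", list(rate = 0.2),
                      censoring = c(admin = 30, rate = 0), seed = 11)
  kh <- kernel_hazard(big)
  mid <- kh$time > 7.5 & kh$time < 22.5
  expect_lt(max(abs(kh$hazard[mid] - 0.2) / 0.2), 0.15)
  expect_true(all(kh$hazard >= 0))

  expect_error(kernel_hazard(ipd_from(time = 1:4, event = 0)), "5 events")
  expect_error(kernel_hazard(big, grid = c(5, 40)), "follow-up")
})

test_that("kernel hazard tracks a binned Nelson-Aalen rate for Weibull data", {
  big <- generate_ipd(20000, "weibull", list(shape = 1.5, scale = 20),
                      censoring = c(admin = 40, rate = 0), seed = 19)
  kh <- kernel_hazard(big, bandwidth = 1.5)
  # piecewise-constant hazard on fine bins: events / person-time at risk
  grid <- kh$time[kh$time > 6 & kh$time < 30]
  binned <- vapply(grid, function(t0) {
    w <- 0.75
    d <- sum(big$time >= t0 - w & big$time < t0 + w & big$event == 1)
    pt <- sum(pmin(pmax(big$time - (t0 - w), 0), 2 * w))
    d / pt
  }, numeric(1))
  est <- hazard_at(kh, grid)
  expect_lt(stats::median(abs(est - binned) / binned), 0.10)

  # invariant to subject ordering
  perm <- big[sample(nrow(big)), ]
  kh2 <- kernel_hazard(as_ipd(as.data.frame(perm), covariates = character()),
                       bandwidth = 1.5)
  expect_equal(kh$hazard, kh2$hazard)
})
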