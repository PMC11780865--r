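test_that("model RMST matches closed forms and adaptive quadrature", {
  m <- stc_model("exponential", baseline = c(rate = 0.1))
  p <- predict_at_population(m, empty_baseline(follow_up = 24))
  expect_equal(rmst_model(p, 10), (1 - exp(-1)) / 0.1, tolerance = 1e-6)

  # S identically 1 integrates to tau
  m1 <- stc_model("exponential", baseline = c(rate = 1e-12))
  p1 <- predict_at_population(m1, empty_baseline(follow_up = 24))
  expect_equal(rmst_model(p1, 12), 12, tolerance = 1e-6)

  expect_error(rmst_model(p, 30), "grid span")
  expect_error(rmst_model(p, -1), "positive")

  # random spline curves against stats::integrate
  set.seed(21)
  for (i in 1:3) {
    knots <- sort(c(0, runif(1, 0.8, 1.8), 2.8))
    gamma <- c(-2.2, 1.1, rnorm(1, 0, 0.3))
    ms <- stc_model("spline", link = sample(c("hazard", "odds"), 1),
                    gamma = gamma, knots = knots)
    ps <- predict_at_population(ms, empty_baseline(follow_up = 30))
    oracle <- stats::integrate(function(t) spline_survival(ms, NULL, t), 0, 20,
                               rel.tol = 1e-10)$value
    expect_equal(rmst_model(ps, 20), oracle, tolerance = 1e-5)
  }
})

test_that("truncation horizon is the shorter follow-up", {
  expect_equal(truncation_horizon(64.8, 46.7), 46.7)
  expect_equal(truncation_horizon(57.8, 70.3), 57.8)
  expect_equal(truncation_horizon(24, 24), 24)
  expect_error(truncation_horizon(-1, 10))
})

test_that("landmark HRs are exact hazard ratios", {
  m <- stc_model("exponential", baseline = c(rate = 0.2))
  big <- generate_ipd(4000, "exponential", list(rate = 0.2),
                      censoring = c(admin = 30, rate = 0), seed = 3)
  kh <- kernel_hazard(big, grid = c(6, 12, 18))
  p <- predict_at_population(m, empty_baseline(follow_up = 30))
  hr <- landmark_hr(p, kh, c(6, 12, 18))
  # identical generating hazards: HR near 1 with exact model numerator
  expect_true(all(abs(hr$hr - 1) < 0.15))

  # identical inputs on both sides give HR = 1 exactly
  hr1 <- landmark_hr(p, kh, c(6, 12), index_hazard = hazard_at(kh, c(6, 12)))
  expect_equal(hr1$hr, c(1, 1))
})

test_that("the dual bootstrap recovers a known RMST difference", {
  idx <- generate_ipd(1500, "exponential", list(rate = 0.1),
                      censoring = c(admin = 14, rate = 0), seed = 41,
                      arm_label = "index")
  cmp <- generate_ipd(1500, "exponential", list(rate = 0.2),
                      censoring = c(admin = 14, rate = 0), seed = 42,
                      arm_label = "comp")
  cfg <- stc_config(bootstrap_B = 100, seed = 5, landmark_times = c(6, 12))
  eff <- bootstrap_compare(idx, cmp,
                           list(family = "exponential", link = NA, m = NA,
                                covariates = character()),
                           empty_baseline(follow_up = 12, label = "comp"), cfg)
  truth <- (1 - exp(-1.2)) / 0.1 - (1 - exp(-2.4)) / 0.2
  est <- eff$estimates
  diff_row <- est[est$estimand == "rmst_diff", ]
  expect_lt(abs(diff_row$median - truth), 0.4)
  expect_equal(eff$tau, 12)
  expect_true(all(est$conf_low <= est$median & est$median <= est$conf_high))
  hr_rows <- est[grepl("^hr_", est$estimand), ]
  expect_true(all(hr_rows$median > 0))
})

test_that("identical seeds reproduce the bootstrap bit for bit", {
  idx <- generate_ipd(200, "exponential", list(rate = 0.12),
                      censoring = c(admin = 24, rate = 0.01), seed = 51)
  cmp <- generate_ipd(200, "exponential", list(rate = 0.15),
                      censoring = c(admin = 24, rate = 0.01), seed = 52)
  cfg <- stc_config(bootstrap_B = 25, seed = 77, landmark_times = c(6, 12))
  run <- function() {
    bootstrap_compare(idx, cmp,
                      list(family = "exponential", link = NA, m = NA,
                           covariates = character()),
                      empty_baseline(follow_up = 20), cfg)
  }
  e1 <- run(); e2 <- run()
  expect_identical(e1$estimates, e2$estimates)
  expect_identical(e1$replicates, e2$replicates)
})

test_that("B = 1 degenerates gracefully", {
  idx <- generate_ipd(100, "exponential", list(rate = 0.1),
                      censoring = c(admin = 24, rate = 0), seed = 61)
  cmp <- generate_ipd(100, "exponential", list(rate = 0.1),
                      censoring = c(admin = 24, rate = 0), seed = 62)
  cfg <- stc_config(bootstrap_B = 1, seed = 9, landmark_times = numeric())
  eff <- bootstrap_compare(idx, cmp,
                           list(family = "exponential", link = NA, m = NA,
                                covariates = character()),
                           empty_baseline(follow_up = 20), cfg)
  est <- eff$estimates[eff$estimates$estimand == "rmst_diff", ]
  expect_equal(est$conf_low, est$median)
  expect_equal(est$conf_high, est$median)
})

test_that("naive KM-only mode agrees with the model at large n under beta = 0", {
  idx <- generate_ipd(3000, "exponential", list(rate = 0.1),
                      censoring = c(admin = 26, rate = 0), seed = 71)
  cmp <- generate_ipd(3000, "exponential", list(rate = 0.16),
                      censoring = c(admin = 26, rate = 0), seed = 72)
  bl <- empty_baseline(follow_up = 24)
  cfg <- stc_config(bootstrap_B = 60, seed = 15, landmark_times = numeric())
  spec <- list(family = "exponential", link = NA, m = NA,
               covariates = character())
  adj <- bootstrap_compare(idx, cmp, spec, bl, cfg)
  nai <- bootstrap_compare(idx, cmp, spec, bl, cfg, naive = TRUE)
  d_adj <- adj$estimates$median[adj$estimates$estimand == "rmst_diff"]
  d_nai <- nai$estimates$median[nai$estimates$estimand == "rmst_diff"]
  expect_lt(abs(d_adj - d_nai), 0.4)
  expect_true(nai$naive)
})
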