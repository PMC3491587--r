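power_model <- function(alpha = 13400, beta = -1.9,
                        tau = c(23, 35, 49, 65, 94, 140)) {
  fit_seasonal_model(data.frame(tau_days = tau, G = alpha * tau^beta))
}

test_that("predict_E is the product of conductance and driving force", {
  m <- power_model()
  expect_identical(predict_E(m, 23, 20, 100), 0)
  expect_identical(predict_E(m, 94, -2, 100), 0)
  # frozen oracle: G'(23) * dPw(20, 50) evaluated independently
  expect_equal(predict_E(m, 23, 20, 50), 0.400344652136034, tolerance = 1e-9)
  # halving the vapour deficit halves the flux
  expect_equal(predict_E(m, 49, 20, 75), predict_E(m, 49, 20, 50) / 2,
               tolerance = 1e-12)
})

test_that("a constant integrand accumulates exactly", {
  flat <- fit_seasonal_model(
    data.frame(tau_days = c(23, 35, 49, 65, 94, 140), G = 10))
  w <- data.frame(
    timestamp = as.POSIXct("2006-06-15 00:00:00", tz = "UTC") + 0:8 * 900,
    T_C = 20, RH_pct = 50)
  s <- predict_series(flat, w, "2006-05-23", step_minutes = 15,
                      window_days = c(23 + 0 / 24, 23 + 1 / 24))
  # one hour at 15-min steps: 4 left-endpoint rectangles summing to E * 1 h
  expect_identical(nrow(s), 4L)
  expect_equal(s$cum[1], s$E_pred[1] * 0.25, tolerance = 1e-12)
  expect_equal(s$cum[4], 10 * delta_pw(20, 50), tolerance = 1e-9)
})

test_that("cumulative series is non-decreasing and chunk-invariant", {
  m <- power_model()
  w <- noisy_weather()
  s <- suppressWarnings(predict_series(m, w, "2006-05-23", 15, c(23, 140)))
  expect_true(all(diff(s$cum) >= 0))
  expect_identical(nrow(s), (140L - 23L) * 96L)
  # accumulate in two windows and concatenate: totals agree
  s1 <- suppressWarnings(predict_series(m, w, "2006-05-23", 15, c(23, 80)))
  s2 <- suppressWarnings(predict_series(m, w, "2006-05-23", 15, c(80, 140)))
  expect_equal(s1$cum[nrow(s1)] + s2$cum[nrow(s2)], s$cum[nrow(s)],
               tolerance = 1e-9)
})

test_that("weather gaps are policed", {
  m <- power_model()
  w <- noisy_weather()
  # carve a 5-h hole: hard error naming the gap
  hole <- w[!(w$timestamp >= as.POSIXct("2006-07-01 06:00:00", tz = "UTC") &
                w$timestamp <= as.POSIXct("2006-07-01 11:00:00", tz = "UTC")), ]
  expect_error(suppressWarnings(
    predict_series(m, hole, "2006-05-23", 15, c(23, 140))), "gap")
  # a 2-h hole is bridged with a warning
  small <- w[!(w$timestamp > as.POSIXct("2006-07-01 06:00:00", tz = "UTC") &
                 w$timestamp <= as.POSIXct("2006-07-01 08:00:00", tz = "UTC")), ]
  expect_warning(predict_series(m, small, "2006-05-23", 15, c(23, 140)),
                 "bridged")
  expect_error(predict_series(m, w, "2006-05-23", 7), "divide")
})

test_that("comparison report recovers identity and scaling", {
  meas <- exp(rnorm(50, 0, 1))
  cmp <- compare_predictions(meas, meas)
  expect_equal(cmp$slope, 1, tolerance = 1e-12)
  expect_equal(cmp$scale, 1, tolerance = 1e-12)
  expect_equal(cmp$r2, 1, tolerance = 1e-12)
  cmp2 <- compare_predictions(2 * meas, meas)
  expect_equal(cmp2$slope, cmp$slope, tolerance = 1e-12)
  expect_equal(cmp2$scale, 2, tolerance = 1e-12)
  expect_error(compare_predictions(c(1, 2), c(1, 2)), ">= 3")
  expect_error(compare_predictions(c(-1, -1, -1, 2), c(1, 1, 1, 2)), ">= 3")
})

test_that("prediction converges on the measurements as noise vanishes", {
  # shrink campaign noise: comparison slope and r2 approach 1
  stats_at <- function(cv, wn) {
    camp <- generate_campaign(
      campaign_scenario(fruit_cv = cv, weight_noise_sd = wn, dim_cv = 0,
                        seed = 77), noisy_weather())
    obs <- build_conductance_dataset(weighings_to_fluxes(camp$weighings),
                                     noisy_weather())
    m <- fit_seasonal_model(obs)
    d <- obs[obs$included, ]
    cmp <- compare_predictions(
      suppressWarnings(predict_E(m, d$tau_days, d$T_C, d$RH_pct)), d$E)
    c(cmp$slope, cmp$r2)
  }
  noisy <- stats_at(0.2, 0.001)
  quiet <- stats_at(0.02, 1e-4)
  expect_gt(quiet[2], noisy[2])
  expect_lt(abs(quiet[1] - 1), 0.02)
  expect_gt(quiet[2], 0.995)
})
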