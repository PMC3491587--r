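test_that("infer_conductance inverts the transpiration model", {
  expect_identical(infer_conductance(0, 0.01), 0)
  expect_equal(infer_conductance(0.4, 0.01155), 34.632, tolerance = 1e-4)
  expect_error(infer_conductance(0.4, 0), "delta_pw")
  # algebraic round trip through the forward model
  m <- fit_seasonal_model(data.frame(tau_days = c(23, 35, 49, 65, 94, 140),
                                     G = 13400 * c(23, 35, 49, 65, 94, 140)^-1.9))
  d <- delta_pw(18, 60)
  E <- predict_E(m, 50, 18, 60)
  expect_equal(infer_conductance(E, d), interpolate_conductance(m, 50),
               tolerance = 1e-12)
})

test_that("weighings difference into per-interval fluxes", {
  empty <- weighings_to_fluxes(noiseless_campaign()$weighings[0, ])
  expect_identical(nrow(empty), 0L)
  fl <- weighings_to_fluxes(noiseless_campaign()$weighings)
  # 25 weighings per fruit -> 24 intervals; 36 fruits over 6 days
  expect_identical(nrow(fl), 36L * 24L)
  expect_true(all(fl$end > fl$start))
  # interval tau is the midpoint of its endpoints (odd multiples of 1/48 day
  # for hourly weighings starting on a whole campaign day)
  expect_true(all(abs((fl$tau_days * 48) %% 2 - 1) < 1e-9))
  expect_error(weighings_to_fluxes(data.frame(fruit_id = "a")), "missing")
})

test_that("conductance dataset pairs fluxes with interval-mean weather", {
  obs <- noiseless_obs()
  expect_s3_class(obs, "kt_flux_obs")
  expect_identical(nrow(obs), 36L * 24L)
  # noiseless records all pass the filters and match generator truth
  expect_true(all(obs$included))
  tr <- noiseless_campaign()$truth
  key <- function(d) paste(d$fruit_id, format(d$timestamp))
  i <- match(key(obs), key(tr))
  expect_false(anyNA(i))
  expect_equal(obs$G, tr$G_true[i], tolerance = 1e-9)
  expect_equal(obs$E, tr$E_true[i], tolerance = 1e-9)

  # empty input round trips to an empty, well-typed table
  empty <- build_conductance_dataset(
    weighings_to_fluxes(noiseless_campaign()$weighings[0, ]),
    noiseless_weather())
  expect_identical(nrow(empty), 0L)

  # saturated air -> retained but excluded with a reason code
  w <- data.frame(timestamp = as.POSIXct("2006-06-15 00:00:00", tz = "UTC") +
                    0:3 * 3600,
                  T_C = 18, RH_pct = 100, W_ms = 1, R_kJ_m2 = 0)
  fl <- data.frame(fruit_id = "x",
                   start = w$timestamp[1], end = w$timestamp[2],
                   tau_days = 23.5, E = 0.01, area_cm2 = 50)
  sat <- build_conductance_dataset(fl, w)
  expect_false(sat$included)
  expect_identical(sat$reason, "zero driving force")

  # flux intervals with no overlapping weather are a pairing error
  fl2 <- within(fl, {start <- start - 86400 * 30; end <- end - 86400 * 30})
  expect_error(build_conductance_dataset(fl2, w), "no weather records")
})

test_that("seasonal power-law fit recovers exact data and handles edge cases", {
  tau <- c(23, 35, 49, 65, 94, 140)
  exact <- data.frame(tau_days = tau, G = 13400 * tau^-1.9)
  m <- fit_seasonal_model(exact)
  expect_equal(m$alpha, 13400, tolerance = 1e-6)
  expect_equal(m$beta, -1.9, tolerance = 1e-6)
  expect_equal(m$tau_range, c(23, 140))

  # flat conductance: beta 0, alpha the common value
  flat <- fit_seasonal_model(data.frame(tau_days = tau, G = 7.5))
  expect_equal(flat$beta, 0, tolerance = 1e-10)
  expect_equal(flat$alpha, 7.5, tolerance = 1e-10)

  expect_error(fit_seasonal_model(exact[1:2, ]), ">= 3")
  expect_error(fit_seasonal_model(data.frame(tau_days = rep(23, 5), G = 1:5)),
               "distinct tau")

  # non-positive-E exclusion changes n_obs but never breaks the fit
  obs <- noisy_obs()
  m_all <- fit_seasonal_model(obs)
  obs2 <- obs
  obs2$included[seq(1, nrow(obs2), by = 7)] <- FALSE
  m_sub <- fit_seasonal_model(obs2)
  expect_lt(m_sub$n_obs, m_all$n_obs)
  expect_equal(m_sub$beta, m_all$beta, tolerance = 0.05)
})

test_that("interpolation follows the power law and flags extrapolation", {
  tau <- c(23, 35, 49, 65, 94, 140)
  m <- fit_seasonal_model(data.frame(tau_days = tau, G = 13400 * tau^-1.9))
  # frozen oracles evaluated independently at 30-digit precision
  expect_equal(interpolate_conductance(m, 23), 34.6594694075056, tolerance = 1e-9)
  expect_equal(interpolate_conductance(m, 140), 1.120628157482, tolerance = 1e-9)
  expect_warning(g1 <- interpolate_conductance(m, 1), "extrapolating")
  expect_equal(g1, m$alpha, tolerance = 1e-12)
  expect_error(interpolate_conductance(m, 0), "positive")
  expect_error(interpolate_conductance(m, -3), "positive")
  # strictly decreasing for beta < 0
  g <- suppressWarnings(interpolate_conductance(m, seq(5, 200, by = 1)))
  expect_true(all(diff(g) < 0))
})

test_that("fit and bootstrap are equivariant under rescaling G", {
  obs <- lognormal_g_obs(11)
  m1 <- fit_seasonal_model(obs)
  bs1 <- bootstrap_ci(obs, n_boot = 50, seed = 99)
  obs10 <- obs
  obs10$G <- obs10$G * 10
  m10 <- fit_seasonal_model(obs10)
  bs10 <- bootstrap_ci(obs10, n_boot = 50, seed = 99)
  expect_equal(m10$alpha, 10 * m1$alpha, tolerance = 1e-9)
  expect_equal(m10$beta, m1$beta, tolerance = 1e-9)
  expect_equal(bs10$alpha_ci, 10 * bs1$alpha_ci, tolerance = 1e-9)
  expect_equal(bs10$beta_ci, bs1$beta_ci, tolerance = 1e-9)
})
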