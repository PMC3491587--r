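#' Weather scenario for the synthetic generator
#'
#' Describes a Mediterranean growing season as deterministic sinusoids plus
#' Gaussian disturbance: air temperature with a seasonal arch (zero at the
#' season edges, maximum mid-season) and a diurnal cycle peaking at
#' `T_peak_hour`; relative humidity in anti-phase with the diurnal
#' temperature cycle; solar radiation as a half-sine over a fixed 06:00-20:00
#' daylight window; windspeed as positive noise about a mean. Radiation is
#' recorded as the energy total per logging interval (kJ m^-2), so its
#' per-record magnitude scales with the cadence.
#'
#' @param season_start First day of the stream (default the full-bloom date
#'   of the emulated season, 2006-05-23).
#' @param season_days Length of the stream, days (default 160: bloom through
#'   harvest with a margin).
#' @param T_base Seasonal-mean air temperature at the season edges, deg C.
#' @param T_seasonal_amp Mid-season temperature excursion, deg C.
#' @param T_diurnal_amp Half-range of the daily temperature cycle, deg C.
#' @param T_peak_hour Local hour of the daily temperature maximum.
#' @param RH_base Mean relative humidity, percent.
#' @param RH_diurnal_amp Half-range of the daily RH cycle, percent
#'   (anti-phase with temperature).
#' @param W_mean Mean windspeed, m s^-1.
#' @param R_max Peak solar radiation on an hourly-total basis, kJ m^-2 h^-1.
#' @param noise_sd Named list of Gaussian disturbance SDs: `T` (deg C),
#'   `RH` (percent), `W` (m s^-1), `R` (kJ m^-2).
#' @param seed Integer RNG seed.
#' @return List of class `"kt_weather_scenario"`.
#' @export
weather_scenario <- function(season_start = "2006-05-23", season_days = 160,
                             T_base = 19, T_seasonal_amp = 8,
                             T_diurnal_amp = 6, T_peak_hour = 14,
                             RH_base = 65, RH_diurnal_amp = 20,
                             W_mean = 2, R_max = 3200,
                             noise_sd = list(T = 0.6, RH = 3, W = 0.8, R = 60),
                             seed = 42L) {
  stopifnot(season_days >= 1, T_peak_hour >= 0, T_peak_hour < 24)
  sc <- list(season_start = as.Date(season_start), season_days = season_days,
             T_base = T_base, T_seasonal_amp = T_seasonal_amp,
             T_diurnal_amp = T_diurnal_amp, T_peak_hour = T_peak_hour,
             RH_base = RH_base, RH_diurnal_amp = RH_diurnal_amp,
             W_mean = W_mean, R_max = R_max, noise_sd = noise_sd,
             seed = as.integer(seed))
  class(sc) <- "kt_weather_scenario"
  sc
}

#' Generate a synthetic weather stream
#'
#' Deterministic function of the scenario (including its seed): the same
#' scenario always yields bit-identical output. The stream covers
#' `[season_start 00:00, season_start + season_days]` inclusive of both
#' endpoints at the requested cadence, with no gaps.
#'
#' @param scenario A [weather_scenario()].
#' @param cadence Logging interval, minutes; 15 or 60.
#' @return Data frame: `timestamp` (POSIXct), `T_C`, `RH_pct` (clamped to
#'   \[2, 100\]), `W_ms` (>= 0), `R_kJ_m2` (0 outside 06:00-20:00).
#' @export
generate_weather <- function(scenario, cadence = 60) {
  stopifnot(inherits(scenario, "kt_weather_scenario"))
  if (!cadence %in% c(15, 60))
    stop("`cadence` must be 15 or 60 minutes", call. = FALSE)
  s <- scenario
  n <- s$season_days * 24 * 60 / cadence + 1
  t0 <- as.POSIXct(paste(s$season_start, "00:00:00"), tz = "UTC")
  ts <- t0 + (seq_len(n) - 1) * cadence * 60
  d <- (seq_len(n) - 1) * cadence / 1440       # days since season start
  h <- (d %% 1) * 24                           # local hour of day
  diurnal <- cos(2 * pi * (h - s$T_peak_hour) / 24)
  with_seed(s$seed, {
    T_c <- s$T_base + s$T_seasonal_amp * sin(pi * d / s$season_days) +
      s$T_diurnal_amp * diurnal + stats::rnorm(n, 0, s$noise_sd$T)
    RH <- s$RH_base - s$RH_diurnal_amp * diurnal +
      stats::rnorm(n, 0, s$noise_sd$RH)
    day <- h >= 6 & h <= 20
    R <- ifelse(day, s$R_max * sin(pi * (h - 6) / 14) * cadence / 60, 0) +
      ifelse(day, stats::rnorm(n, 0, s$noise_sd$R), 0)
    W <- pmax(s$W_mean + stats::rnorm(n, 0, s$noise_sd$W), 0)
  })
  data.frame(timestamp = ts,
             T_C = T_c,
             RH_pct = pmin(pmax(RH, 2), 100),
             W_ms = W,
             R_kJ_m2 = pmax(R, 0))
}

#' Weighing-campaign scenario for the synthetic generator
#'
#' Describes replicated 24-h gravimetric campaigns on a set of days after
#' full bloom. Each fruit carries a lognormal conductance multiplier
#' (median 1, SD `fruit_cv` on the log scale) representing fruit-to-fruit
#' variability in skin conductance; its dimensions follow a saturating
#' growth curve with small lognormal scatter, and its initial weight is the
#' ellipsoid-volume estimate 0.55 * length * width^2 (g). Balance noise is
#' additive Gaussian on each recorded weight.
#'
#' @param full_bloom Full-bloom date (default 2006-05-23); tau is days since
#'   00:00 on this date.
#' @param campaign_days Days after full bloom of the weighing campaigns
#'   (default `c(23, 35, 49, 65, 94, 140)`).
#' @param fruits_per_day Replicate fruits per campaign day (default 6).
#' @param weighing_hours Campaign duration at hourly cadence (default 24,
#'   giving 25 weighings per fruit).
#' @param true_alpha,true_beta Generating conductance law
#'   G = alpha * tau^beta (defaults 13400, -1.90).
#' @param fruit_cv Lognormal SD of the per-fruit conductance multiplier
#'   (default 0.2).
#' @param weight_noise_sd Balance noise SD, g (default 0.001; one count of
#'   the 1-mg research balance used in such campaigns).
#' @param dim_cv Lognormal SD of per-fruit dimension scatter (default 0.05).
#' @param seed Integer RNG seed.
#' @return List of class `"kt_campaign_scenario"`.
#' @export
campaign_scenario <- function(full_bloom = "2006-05-23",
                              campaign_days = c(23, 35, 49, 65, 94, 140),
                              fruits_per_day = 6, weighing_hours = 24,
                              true_alpha = 13400, true_beta = -1.90,
                              fruit_cv = 0.2, weight_noise_sd = 0.001,
                              dim_cv = 0.05, seed = 7L) {
  stopifnot(length(campaign_days) >= 1, fruits_per_day >= 1,
            weighing_hours >= 1, true_alpha > 0)
  sc <- list(full_bloom = as.Date(full_bloom), campaign_days = campaign_days,
             fruits_per_day = fruits_per_day, weighing_hours = weighing_hours,
             true_alpha = true_alpha, true_beta = true_beta,
             fruit_cv = fruit_cv, weight_noise_sd = weight_noise_sd,
             dim_cv = dim_cv, seed = as.integer(seed))
  class(sc) <- "kt_campaign_scenario"
  sc
}

# Saturating Hayward fruit-length growth curve, cm, vs days after full bloom.
.kt_mean_length <- function(tau) 6.5 - 4.0 * exp(-tau / 40)
.kt_width_ratio <- 0.78

#' Generate a synthetic fruit weighing campaign with hidden truth
#'
#' For each campaign day and fruit, hourly weights are produced by stepping
#' the mass balance dm/dt = E_true * area * M / 1000 (g h^-1) with
#' E_true = alpha * tau^beta * multiplier * dPw, where tau is evaluated at
#' each hour's midpoint and dPw at that hour's mean weather — the same
#' pairing the estimation stage uses, so with all noise at zero the
#' round trip from weights back to (alpha, beta) is exact. Balance noise is
#' then added to the recorded weights. The hidden truth table (per-fruit
#' multiplier, per-interval G_true and E_true) is returned alongside for
#' recovery tests; it satisfies E_true = G_true * dPw identically.
#'
#' @param cs A [campaign_scenario()].
#' @param weather Weather data frame covering every campaign window.
#' @param pressure Atmospheric pressure, Pa.
#' @return List with `weighings` (fruit_id, timestamp, tau_days, weight_g,
#'   length_cm, width_cm) and `truth` (fruit_id, timestamp, tau_days,
#'   multiplier, delta_pw, G_true, E_true).
#' @export
generate_campaign <- function(cs, weather, pressure = .kt_pressure_default) {
  stopifnot(inherits(cs, "kt_campaign_scenario"))
  check_columns(weather, c("timestamp", "T_C", "RH_pct"), "weather")
  weather <- weather[order(weather$timestamp), , drop = FALSE]
  wt <- as.numeric(weather$timestamp)
  bloom <- as.POSIXct(paste(cs$full_bloom, "00:00:00"), tz = "UTC")
  span_ok <- as.numeric(bloom) + cs$campaign_days * 86400
  bad <- span_ok < wt[1] | (span_ok + cs$weighing_hours * 3600) > wt[length(wt)]
  if (any(bad))
    stop("weather does not cover campaign day(s) ",
         paste(cs$campaign_days[bad], collapse = ", "), " after full bloom",
         call. = FALSE)

  weigh <- list(); truth <- list()
  with_seed(cs$seed, {
    for (d in cs$campaign_days) {
      for (j in seq_len(cs$fruits_per_day)) {
        id <- sprintf("d%03d_f%02d", d, j)
        mult <- exp(stats::rnorm(1, 0, cs$fruit_cv))
        len <- .kt_mean_length(d) * exp(stats::rnorm(1, 0, cs$dim_cv))
        wid <- .kt_width_ratio * len
        area <- fruit_surface_area(len, wid)
        w0 <- 0.55 * len * wid^2
        t_rec <- bloom + d * 86400 + (0:cs$weighing_hours) * 3600
        tr <- as.numeric(t_rec)
        # hourly mean weather per interval (same pairing as estimation)
        dpw <- G_true <- E_true <- numeric(cs$weighing_hours)
        for (k in seq_len(cs$weighing_hours)) {
          idx <- which(wt >= tr[k] & wt < tr[k + 1])
          if (length(idx) == 0)
            stop("no weather record covers hour ", k, " of campaign day ", d,
                 call. = FALSE)
          dpw[k] <- delta_pw(mean(weather$T_C[idx]),
                             mean(weather$RH_pct[idx]), P = pressure)
          tau_mid <- d + (k - 0.5) / 24
          G_true[k] <- cs$true_alpha * tau_mid^cs$true_beta * mult
          E_true[k] <- G_true[k] * dpw[k]
        }
        dm <- E_true * area * .kt_molar_mass_water / 1000   # g per hour
        w <- w0 - cumsum(c(0, dm))
        if (any(w <= 0))
          stop("fruit ", id, " transpired its whole mass; unrealistic scenario",
               call. = FALSE)
        w_rec <- w + stats::rnorm(length(w), 0, cs$weight_noise_sd)
        weigh[[length(weigh) + 1L]] <- data.frame(
          fruit_id = id, timestamp = t_rec,
          tau_days = (tr - as.numeric(bloom)) / 86400,
          weight_g = w_rec, length_cm = len, width_cm = wid)
        truth[[length(truth) + 1L]] <- data.frame(
          fruit_id = id, timestamp = t_rec[-length(t_rec)],
          tau_days = d + (seq_len(cs$weighing_hours) - 0.5) / 24,
          multiplier = mult, delta_pw = dpw, G_true = G_true, E_true = E_true)
      }
    }
  })
  weigh <- do.call(rbind, weigh); rownames(weigh) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(weighings = weigh, truth = truth)
}

#' Write a synthetic fixture to disk (and read it back)
#'
#' Writes `weather.csv`, `weighings.csv`, `truth.csv` and a JSON snapshot of
#' both scenarios to a directory. Numeric columns are serialised with 17
#' significant digits so that re-reading reproduces the streams bit-exactly.
#'
#' @param weather,weighings,truth Data frames as produced by
#'   [generate_weather()] and [generate_campaign()].
#' @param dir Output directory (created if absent).
#' @param scenarios Optional list of scenario objects stored as
#'   `scenario.json` alongside the data.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(weather, weighings, truth, dir, scenarios = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kt_write_csv(weather, file.path(dir, "weather.csv"))
  kt_write_csv(weighings, file.path(dir, "weighings.csv"))
  kt_write_csv(truth, file.path(dir, "truth.csv"))
  if (!is.null(scenarios)) {
    sc <- lapply(scenarios, function(s) {
      s <- unclass(s)
      s[vapply(s, inherits, logical(1), what = "Date")] <-
        lapply(s[vapply(s, inherits, logical(1), what = "Date")], as.character)
      s
    })
    jsonlite::write_json(sc, file.path(dir, "scenario.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  list(weather = read_weather(file.path(dir, "weather.csv")),
       weighings = read_weighings(file.path(dir, "weighings.csv")),
       truth = kt_read_csv(file.path(dir, "truth.csv")))
}
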