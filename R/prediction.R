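#' Predict instantaneous fruit transpiration
#'
#' Forward Fick's-law prediction \eqn{E' = G'(\tau) \times \Delta P_w(T, RH)}
#' for a fruit of developmental age `tau` (days after full bloom) in air at
#' temperature `T_c` and relative humidity `RH`.
#'
#' @param model Fitted `"kt_conductance_model"`.
#' @param tau Days after full bloom (> 0). Vectorised with `T_c`, `RH`.
#' @param T_c Air temperature, degrees Celsius.
#' @param RH Relative humidity, percent.
#' @param P Atmospheric pressure, Pa.
#' @return Predicted transpiration rate E', mmol cm^-2 h^-1 (always >= 0).
#' @export
predict_E <- function(model, tau, T_c, RH, P = .kt_pressure_default) {
  interpolate_conductance(model, tau) * delta_pw(T_c, RH, P = P)
}

#' Predict and accumulate transpiration over a season of weather
#'
#' Resamples the weather stream onto a regular grid (linear interpolation of
#' T and RH), predicts E' at every grid point, and accumulates with a
#' left-rectangle rule: each grid value is held for one step, so
#' `cum[k] = cum[k-1] + E'[k] * step/60` in mmol cm^-2 (per unit fruit
#' surface area). Gaps in the weather record longer than `max_gap_hours` are
#' an error (listing the offending intervals); shorter gaps are interpolated
#' across with a warning.
#'
#' The default window, 10 to 150 days after full bloom, slightly exceeds the
#' 23-140 day range over which the conductance model is typically fitted;
#' extrapolation outside the fitted range is flagged by
#' [interpolate_conductance()]. The grid is clipped to the weather span.
#'
#' @param model Fitted `"kt_conductance_model"`.
#' @param weather Weather data frame (`timestamp`, `T_C`, `RH_pct`, ...);
#'   windspeed and radiation columns are accepted and ignored.
#' @param full_bloom Full-bloom date (`Date`, POSIXct, or string); tau is
#'   measured from 00:00 on this date.
#' @param step_minutes Grid spacing, minutes; must divide 60 (default 15).
#' @param window_days Length-2 numeric, prediction window in days after full
#'   bloom (default `c(10, 150)`).
#' @param P Atmospheric pressure, Pa.
#' @param max_gap_hours Longest weather gap bridged by interpolation
#'   (default 3).
#' @return Data frame of class `"kt_cumulative_series"`: `timestamp`,
#'   `tau_days`, `E_pred` (mmol cm^-2 h^-1), `cum` (mmol cm^-2), with
#'   attribute `step_minutes`.
#' @export
predict_series <- function(model, weather, full_bloom, step_minutes = 15,
                           window_days = c(10, 150),
                           P = .kt_pressure_default, max_gap_hours = 3) {
  check_columns(weather, c("timestamp", "T_C", "RH_pct"), "weather")
  if (60 %% step_minutes != 0)
    stop("`step_minutes` must divide 60", call. = FALSE)
  weather <- weather[order(weather$timestamp), , drop = FALSE]
  wt <- as.numeric(weather$timestamp)
  gaps <- diff(wt)
  too_long <- which(gaps > max_gap_hours * 3600)
  if (length(too_long))
    stop("weather gaps longer than ", max_gap_hours, " h at: ",
         paste(utils::head(format(weather$timestamp[too_long]), 5),
               collapse = "; "), call. = FALSE)
  cadence <- stats::median(gaps)
  if (any(gaps > 1.5 * cadence))
    warning(sum(gaps > 1.5 * cadence),
            " short weather gap(s) bridged by interpolation", call. = FALSE)

  bloom <- as.POSIXct(paste(as.Date(full_bloom), "00:00:00"), tz = "UTC")
  t0 <- max(as.numeric(bloom) + window_days[1] * 86400, wt[1])
  t1 <- min(as.numeric(bloom) + window_days[2] * 86400, wt[length(wt)])
  if (t1 <= t0) stop("prediction window does not overlap the weather span",
                     call. = FALSE)
  # left endpoints of the rectangle steps covering [t0, t1)
  grid <- seq(t0, t1, by = step_minutes * 60)
  grid <- grid[grid < t1]
  if (length(grid) == 0)
    stop("prediction window shorter than one step", call. = FALSE)
  T_g <- stats::approx(wt, weather$T_C, xout = grid)$y
  RH_g <- pmin(pmax(stats::approx(wt, weather$RH_pct, xout = grid)$y, 0), 100)
  tau <- (grid - as.numeric(bloom)) / 86400
  E <- predict_E(model, tau, T_g, RH_g, P = P)
  out <- data.frame(
    timestamp = as.POSIXct(grid, origin = "1970-01-01", tz = "UTC"),
    tau_days = tau, E_pred = E,
    cum = cumsum(E * step_minutes / 60)
  )
  attr(out, "step_minutes") <- step_minutes
  class(out) <- c("kt_cumulative_series", "data.frame")
  out
}

#' Compare predicted with measured transpiration on the log scale
#'
#' OLS of log E' on log E over pairs where both are positive, summarising
#' agreement as the power relation \eqn{E' = \mathrm{scale} \times
#' E^{\mathrm{slope}}}; a perfect model gives scale 1, slope 1 and R^2 = 1 on
#' the log scale. One predicted value may legitimately pair with several
#' replicate measurements from the same hour; pass them as repeated entries.
#'
#' @param pred Predicted rates E', mmol cm^-2 h^-1.
#' @param meas Paired measured rates E, same length and units.
#' @return Object of class `"kt_comparison"`: list with `n`, `slope`
#'   (the exponent), `scale` (back-transformed intercept), `r2` (log scale).
#' @export
compare_predictions <- function(pred, meas) {
  if (length(pred) != length(meas))
    stop("`pred` and `meas` must have equal length", call. = FALSE)
  ok <- is.finite(pred) & is.finite(meas) & pred > 0 & meas > 0
  if (sum(ok) < 3)
    stop("need >= 3 pairs with both values positive", call. = FALSE)
  fit <- stats::lm(log(pred[ok]) ~ log(meas[ok]))
  out <- list(
    n = sum(ok),
    slope = unname(stats::coef(fit)[2]),
    scale = exp(unname(stats::coef(fit)[1])),
    r2 = summary(fit)$r.squared
  )
  class(out) <- "kt_comparison"
  out
}

#' @export
print.kt_comparison <- function(x, ...) {
  cat(sprintf(
    "Predicted vs measured transpiration (log-log OLS, n = %d):\n", x$n))
  cat(sprintf("  E' = %.4g * E^%.4g   (R2 = %.3f on the log scale)\n",
              x$scale, x$slope, x$r2))
  invisible(x)
}
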