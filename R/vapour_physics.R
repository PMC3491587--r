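#' kiwitrans: Fick's-law modelling of kiwifruit transpiration
#'
#' Transpiration from the surface of a fruit is modelled as a molar flux
#' density \eqn{E = G \times \Delta P_w} (mmol cm^-2 h^-1), the product of a
#' skin conductance \eqn{G} and the dimensionless mol-fraction difference in
#' water vapour between the saturated fruit interior and the ambient air.
#' Kiwifruit skin has no active stomata, so \eqn{G} does not cycle diurnally
#' and declines developmentally; the package estimates that decline as a
#' power law in days after full bloom and uses it to predict transpiration
#' from weather-station temperature and relative-humidity records.
#'
#' @section Units:
#' Areas are cm^2, fluxes mmol cm^-2 h^-1, pressures Pa, temperatures degrees
#' Celsius, conductances mmol cm^-2 h^-1. No internal SI conversion is done.
#'
#' @keywords internal
"_PACKAGE"

#' Physical constants and defaults
#'
#' Standard sea-level atmospheric pressure (Pa) and the molar mass of water
#' (g mol^-1), used wherever the caller does not override them. The fruit
#' surface-area coefficients are from a planimeter calibration on Hayward
#' kiwifruit skins: A = a + b * pi * length * width.
#'
#' @name kiwitrans-constants
#' @keywords internal
NULL

.kt_pressure_default <- 101325      # Pa, standard atmosphere; site near sea level
.kt_molar_mass_water <- 18.015      # g mol^-1
.kt_area_a_default <- 0.798         # cm^2, calibration intercept
.kt_area_b_default <- 1.0078        # dimensionless calibration slope

#' Saturated vapour pressure of water
#'
#' Exponential approximation \eqn{p = 610.7\, e^{17.4 T / (239 + T)}} for the
#' equilibrium water-vapour pressure over a plane water surface at air
#' temperature `T`. At 0 degrees C the exponent vanishes and the function
#' returns exactly 610.7 Pa.
#'
#' @param T_c Air temperature, degrees Celsius. Must exceed -239 (the
#'   denominator of the exponent); sensible use is roughly -20 to 50.
#' @return Saturated vapour pressure, Pa. Vectorised over `T_c`.
#' @examples
#' saturated_vapour_pressure(0)    # 610.7
#' saturated_vapour_pressure(20)   # ~2340 Pa
#' @export
saturated_vapour_pressure <- function(T_c) {
  if (!is.numeric(T_c)) stop("`T_c` must be numeric", call. = FALSE)
  if (any(T_c <= -239, na.rm = TRUE))
    stop("`T_c` must be > -239 degrees C (denominator 239 + T must be positive)",
         call. = FALSE)
  610.7 * exp(17.4 * T_c / (239 + T_c))
}

#' Mol-fraction water-vapour difference (driving force)
#'
#' The dimensionless driving force of Fick's-law transpiration,
#' \eqn{\Delta P_w = (p_i - p_a) / P}, taking the fruit's internal air spaces
#' as water-saturated at air temperature (`p_i = p(T)`) and the ambient
#' vapour pressure as `p_a = p(T) * RH / 100`, so
#' \eqn{\Delta P_w = p(T)(1 - RH/100)/P}.
#'
#' Relative humidities slightly above 100 % (common sensor overshoot, up to
#' 102) are clamped to 100 with a warning; larger values are an error.
#'
#' @param T_c Air temperature, degrees Celsius.
#' @param RH Relative humidity, percent, in \[0, 100\].
#' @param P Atmospheric pressure, Pa (default 101325).
#' @return Dimensionless mol-fraction difference, in \[0, p(T)/P\].
#'   Vectorised over `T_c` and `RH`.
#' @examples
#' delta_pw(20, 100)  # 0: saturated air
#' delta_pw(20, 50)   # ~0.0116
#' @export
delta_pw <- function(T_c, RH, P = .kt_pressure_default) {
  if (!is.numeric(P) || any(P <= 0)) stop("`P` must be > 0 Pa", call. = FALSE)
  RH <- clamp_rh(RH)
  saturated_vapour_pressure(T_c) * (1 - RH / 100) / P
}

# RH validation shared by delta_pw and the readers: values in (100, 102]
# are treated as sensor overshoot and clamped; anything else out of range
# is a hard error.
clamp_rh <- function(RH) {
  if (!is.numeric(RH)) stop("`RH` must be numeric", call. = FALSE)
  bad <- !is.na(RH) & (RH < 0 | RH > 102)
  if (any(bad))
    stop("RH outside [0, 102]: ", paste(utils::head(RH[bad], 5), collapse = ", "),
         call. = FALSE)
  over <- !is.na(RH) & RH > 100
  if (any(over)) {
    warning(sum(over), " RH value(s) in (100, 102] clamped to 100",
            call. = FALSE)
    RH[over] <- 100
  }
  RH
}

#' Kiwifruit surface area from its two major dimensions
#'
#' Planimeter-calibrated linear model \eqn{A = a + b \pi L W} relating the
#' peeled-skin surface area of a Hayward kiwifruit to its length `L` and
#' maximum width `W` (both cm).
#'
#' @param length_cm Fruit length, cm (> 0).
#' @param width_cm Maximum fruit width, cm (> 0).
#' @param a Calibration intercept, cm^2 (default 0.798).
#' @param b Calibration slope, dimensionless (default 1.0078).
#' @return Surface area, cm^2. Vectorised.
#' @examples
#' fruit_surface_area(6, 5)  # ~95.8 cm^2
#' @export
fruit_surface_area <- function(length_cm, width_cm,
                               a = .kt_area_a_default,
                               b = .kt_area_b_default) {
  if (any(length_cm <= 0, na.rm = TRUE) || any(width_cm <= 0, na.rm = TRUE))
    stop("fruit dimensions must be positive", call. = FALSE)
  a + b * pi * length_cm * width_cm
}

#' Gravimetric weight loss to molar flux density
#'
#' Converts a weight drop over an interval into a transpiration rate per unit
#' fruit surface area: \eqn{E = (w_\mathrm{start} - w_\mathrm{end}) / M
#' \times 1000 / (A \, \Delta t)} in mmol cm^-2 h^-1. The result may be
#' negative for noisy input (apparent weight gain); filtering is the
#' caller's decision.
#'
#' @param w_start,w_end Fruit weights at interval start and end, g.
#' @param dt_h Interval length, h (> 0).
#' @param area_cm2 Fruit surface area, cm^2 (> 0).
#' @param molar_mass Molar mass of water, g mol^-1 (default 18.015).
#' @return Molar flux density, mmol cm^-2 h^-1. Vectorised.
#' @examples
#' weight_loss_to_flux(100.18015, 100, 1, 100)  # 0.1
#' @export
weight_loss_to_flux <- function(w_start, w_end, dt_h, area_cm2,
                                molar_mass = .kt_molar_mass_water) {
  if (any(dt_h <= 0, na.rm = TRUE)) stop("`dt_h` must be > 0", call. = FALSE)
  if (any(area_cm2 <= 0, na.rm = TRUE)) stop("`area_cm2` must be > 0", call. = FALSE)
  (w_start - w_end) / molar_mass * 1000 / (area_cm2 * dt_h)
}
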