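#' Infer skin conductance from a measured flux and its driving force
#'
#' Rearranges the Fick's-law transpiration model \eqn{E = G \Delta P_w} as
#' \eqn{G = E / \Delta P_w}. Undefined when the driving force vanishes:
#' near-saturated air carries no information about conductance.
#'
#' @param E Transpiration rate, mmol cm^-2 h^-1.
#' @param dpw Dimensionless mol-fraction difference (> 0).
#' @return Conductance, mmol cm^-2 h^-1. Vectorised.
#' @export
infer_conductance <- function(E, dpw) {
  if (any(dpw <= 0, na.rm = TRUE))
    stop("conductance undefined for delta_pw <= 0; exclude those records",
         call. = FALSE)
  E / dpw
}

#' Per-interval fluxes from a fruit weighing campaign
#'
#' Differences consecutive weighings of each fruit into interval transpiration
#' rates. Fruit surface area is computed from the recorded length and maximum
#' width; the interval is stamped with the midpoint of its endpoints' tau
#' (days after full bloom), so conductance inferred from the interval is
#' attributed to the middle of the hour it spans.
#'
#' @param weighings Data frame with columns `fruit_id`, `timestamp` (POSIXct),
#'   `tau_days`, `weight_g`, `length_cm`, `width_cm`.
#' @param a,b Surface-area calibration coefficients (see
#'   [fruit_surface_area()]).
#' @param molar_mass Molar mass of water, g mol^-1.
#' @return Data frame of flux intervals: `fruit_id`, `start`, `end`,
#'   `tau_days`, `E` (mmol cm^-2 h^-1), `area_cm2`.
#' @export
weighings_to_fluxes <- function(weighings, a = .kt_area_a_default,
                                b = .kt_area_b_default,
                                molar_mass = .kt_molar_mass_water) {
  need <- c("fruit_id", "timestamp", "tau_days", "weight_g",
            "length_cm", "width_cm")
  check_columns(weighings, need, "weighings")
  if (nrow(weighings) == 0) {
    return(data.frame(fruit_id = character(), start = as.POSIXct(character()),
                      end = as.POSIXct(character()), tau_days = numeric(),
                      E = numeric(), area_cm2 = numeric()))
  }
  sp <- split(weighings, weighings$fruit_id)
  out <- lapply(sp, function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    if (nrow(d) < 2) return(NULL)
    k <- seq_len(nrow(d) - 1L)
    dt_h <- as.numeric(difftime(d$timestamp[k + 1L], d$timestamp[k],
                                units = "hours"))
    area <- fruit_surface_area(d$length_cm[k], d$width_cm[k], a = a, b = b)
    data.frame(
      fruit_id = d$fruit_id[k],
      start = d$timestamp[k],
      end = d$timestamp[k + 1L],
      tau_days = (d$tau_days[k] + d$tau_days[k + 1L]) / 2,
      E = weight_loss_to_flux(d$weight_g[k], d$weight_g[k + 1L], dt_h, area,
                              molar_mass = molar_mass),
      area_cm2 = area
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build the conductance dataset from flux intervals and weather
#'
#' Pairs each flux interval with the mean of the weather records it covers,
#' computes the driving force from the mean temperature and relative
#' humidity, and infers conductance G = E / dPw. Records failing the
#' inclusion filters are retained with `included = FALSE` and a reason code,
#' so the excluded fraction is auditable.
#'
#' Inclusion requires a positive measured flux (transpiration, not
#' condensation) and a driving force above `delta_pw_min`; near-saturated
#' intervals make G a ratio of two near-zero noisy numbers.
#'
#' @param fluxes Flux-interval data frame from [weighings_to_fluxes()].
#' @param weather Weather data frame: `timestamp`, `T_C`, `RH_pct`, `W_ms`,
#'   `R_kJ_m2`.
#' @param pressure Atmospheric pressure, Pa.
#' @param delta_pw_min Minimum driving force for inclusion (default 1e-4,
#'   dimensionless).
#' @param positive_E_only Exclude intervals with E <= 0 (default TRUE).
#' @return Data frame of flux observations (class `"kt_flux_obs"`):
#'   `fruit_id`, `timestamp`, `tau_days`, `E`, `T_C`, `RH_pct`, `W_ms`,
#'   `R_kJ_m2`, `delta_pw`, `G`, `included`, `reason`.
#' @export
build_conductance_dataset <- function(fluxes, weather,
                                      pressure = .kt_pressure_default,
                                      delta_pw_min = 1e-4,
                                      positive_E_only = TRUE) {
  check_columns(weather, c("timestamp", "T_C", "RH_pct"), "weather")
  if (nrow(fluxes) == 0) {
    out <- data.frame(fruit_id = character(), timestamp = as.POSIXct(character()),
                      tau_days = numeric(), E = numeric(), T_C = numeric(),
                      RH_pct = numeric(), W_ms = numeric(), R_kJ_m2 = numeric(),
                      delta_pw = numeric(), G = numeric(), included = logical(),
                      reason = character())
    class(out) <- c("kt_flux_obs", "data.frame")
    return(out)
  }
  weather <- weather[order(weather$timestamp), , drop = FALSE]
  wt <- as.numeric(weather$timestamp)
  s <- as.numeric(fluxes$start)
  e <- as.numeric(fluxes$end)
  n <- nrow(fluxes)
  Tm <- RHm <- Wm <- Rm <- rep(NA_real_, n)
  orphan <- logical(n)
  has_w <- "W_ms" %in% names(weather)
  has_r <- "R_kJ_m2" %in% names(weather)
  for (i in seq_len(n)) {
    idx <- which(wt >= s[i] & wt < e[i])
    if (length(idx) == 0) { orphan[i] <- TRUE; next }
    Tm[i] <- mean(weather$T_C[idx])
    RHm[i] <- mean(weather$RH_pct[idx])
    if (has_w) Wm[i] <- mean(weather$W_ms[idx])
    if (has_r) Rm[i] <- mean(weather$R_kJ_m2[idx])
  }
  if (any(orphan))
    stop("no weather records overlap ", sum(orphan), " flux interval(s), e.g. ",
         paste(utils::head(format(fluxes$start[orphan]), 3), collapse = "; "),
         call. = FALSE)
  dpw <- delta_pw(Tm, RHm, P = pressure)
  reason <- rep("ok", n)
  reason[positive_E_only & fluxes$E <= 0] <- "non-positive E"
  reason[dpw <= delta_pw_min] <- "zero driving force"
  included <- reason == "ok"
  G <- ifelse(dpw > 0, fluxes$E / dpw, NA_real_)
  out <- data.frame(
    fruit_id = fluxes$fruit_id, timestamp = fluxes$start,
    tau_days = fluxes$tau_days, E = fluxes$E,
    T_C = Tm, RH_pct = RHm, W_ms = Wm, R_kJ_m2 = Rm,
    delta_pw = dpw, G = G, included = included, reason = reason
  )
  class(out) <- c("kt_flux_obs", "data.frame")
  out
}

# Closed-form OLS of y on x returning c(intercept, slope); used in the
# bootstrap and jackknife loops where lm() overhead would dominate.
.ols2 <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  b <- sum((x - mx) * (y - my)) / sxx
  c(my - b * mx, b)
}

#' Fit the seasonal power-law conductance model
#'
#' Ordinary least squares of log G on log tau over the included observations,
#' back-transformed to the power law \eqn{G'(\tau) = \alpha \tau^{\beta}}.
#' Natural logarithms are used internally; the point estimates are invariant
#' to the log base. The adjusted R^2 is reported on the log scale, where the
#' fit is performed.
#'
#' @param obs Flux-observation data frame from [build_conductance_dataset()],
#'   or any data frame with numeric `G` and `tau_days` columns (an `included`
#'   column, if present, subsets the fit).
#' @return An object of class `"kt_conductance_model"`: list with `alpha`,
#'   `beta`, `alpha_ci`, `beta_ci` (NULL until [bootstrap_ci()] fills them),
#'   `adj_r2`, `n_obs`, `tau_range`.
#' @export
fit_seasonal_model <- function(obs) {
  d <- included_obs(obs)
  if (nrow(d) < 3) stop("need >= 3 included observations", call. = FALSE)
  lt <- log(d$tau_days)
  lg <- log(d$G)
  if (length(unique(d$tau_days)) < 2 || var(lt) == 0)
    stop("log tau has zero variance; need >= 2 distinct tau values",
         call. = FALSE)
  fit <- stats::lm(lg ~ lt)
  co <- stats::coef(fit)
  model <- list(
    alpha = exp(unname(co[1])),
    beta = unname(co[2]),
    alpha_ci = NULL, beta_ci = NULL,
    adj_r2 = summary(fit)$adj.r.squared,
    n_obs = nrow(d),
    tau_range = range(d$tau_days),
    bootstrap = NULL
  )
  class(model) <- "kt_conductance_model"
  model
}

# Shared subsetting: honour an `included` flag if present, then require
# positive G and tau so logs are defined.
included_obs <- function(obs) {
  check_columns(obs, c("G", "tau_days"), "obs")
  d <- as.data.frame(obs)
  if ("included" %in% names(d)) d <- d[d$included, , drop = FALSE]
  d[is.finite(d$G) & d$G > 0 & d$tau_days > 0, , drop = FALSE]
}

#' Interpolate (or mildly extrapolate) seasonal conductance
#'
#' Evaluates the fitted power law \eqn{G'(\tau) = \alpha \tau^{\beta}}.
#' Requests outside the fitted tau range are honoured with an extrapolation
#' warning: the decline is smooth enough that limited extrapolation beyond
#' the first and last measurement days is defensible, but it is flagged.
#'
#' @param model A `"kt_conductance_model"`.
#' @param tau Days after full bloom (> 0). Vectorised.
#' @return Conductance G', mmol cm^-2 h^-1.
#' @export
interpolate_conductance <- function(model, tau) {
  stopifnot(inherits(model, "kt_conductance_model"))
  if (any(tau <= 0, na.rm = TRUE))
    stop("`tau` must be positive (days after full bloom)", call. = FALSE)
  if (!is.null(model$tau_range)) {
    out_of <- tau < model$tau_range[1] | tau > model$tau_range[2]
    if (any(out_of, na.rm = TRUE))
      warning(sum(out_of, na.rm = TRUE), " tau value(s) outside the fitted ",
              "range [", signif(model$tau_range[1], 4), ", ",
              signif(model$tau_range[2], 4), "]: extrapolating", call. = FALSE)
  }
  model$alpha * tau^model$beta
}

#' @export
print.kt_conductance_model <- function(x, ...) {
  cat("Seasonal skin-conductance model G'(tau) = alpha * tau^beta\n")
  cat(sprintf("  alpha = %.4g  beta = %.4g  (n = %d, adj R2 = %.3f)\n",
              x$alpha, x$beta, x$n_obs, x$adj_r2))
  if (!is.null(x$alpha_ci))
    cat(sprintf("  95%% CI alpha: [%.4g, %.4g]  beta: [%.4g, %.4g]\n",
                x$alpha_ci[1], x$alpha_ci[2], x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("  fitted tau range: %.3g to %.3g days after full bloom\n",
              x$tau_range[1], x$tau_range[2]))
  invisible(x)
}

check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(df)
}
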