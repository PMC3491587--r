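# Shared synthetic fixtures, built once per test run and cached.

.kt_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .kt_cache)) assign(key, expr, envir = .kt_cache)
  get(key, envir = .kt_cache)
}

# Noiseless season: deterministic weather + exact-law campaign.
noiseless_weather <- function() cached("nw", {
  generate_weather(weather_scenario(noise_sd = list(T = 0, RH = 0, W = 0, R = 0)),
                   cadence = 60)
})

noiseless_campaign <- function() cached("nc", {
  generate_campaign(campaign_scenario(fruit_cv = 0, weight_noise_sd = 0,
                                      dim_cv = 0),
                    noiseless_weather())
})

noiseless_obs <- function() cached("nobs", {
  build_conductance_dataset(
    weighings_to_fluxes(noiseless_campaign()$weighings), noiseless_weather())
})

# Default noisy season (the generator's stated world).
noisy_weather <- function() cached("yw", {
  generate_weather(weather_scenario(), cadence = 60)
})

noisy_obs <- function() cached("yobs", {
  camp <- generate_campaign(campaign_scenario(), noisy_weather())
  build_conductance_dataset(weighings_to_fluxes(camp$weighings),
                            noisy_weather())
})

# Direct conductance draws: G = alpha * tau^beta * lognormal(sigma), iid.
lognormal_g_obs <- function(seed, sigma = 0.2, n_per_day = 100,
                            alpha = 13400, beta = -1.9,
                            days = c(23, 35, 49, 65, 94, 140)) {
  set.seed(seed)
  tau <- rep(days, each = n_per_day)
  n <- length(tau)
  data.frame(tau_days = tau,
             G = alpha * tau^beta * exp(rnorm(n, 0, sigma)),
             W_ms = pmax(rnorm(n, 2, 0.8), 0),
             R_kJ_m2 = runif(n, 0, 3000),
             included = TRUE)
}
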