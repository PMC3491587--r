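# kiwitrans

Fick's-law modelling of kiwifruit transpiration from standard weather-station
data.

## The problem

Water loss from a growing kiwifruit berry matters well beyond the water
itself: transpiration drives the xylem stream that imports calcium into the
fruit, and calcium status in turn shapes storage quality. Quantifying fruit
transpiration continuously over a season is therefore useful to physiologists
and horticulturists — but it is only ever *measured* gravimetrically, in
short hourly weighing campaigns on a handful of days. `kiwitrans` turns those
sparse campaigns plus routine weather records into a season-long transpiration
model.

The model is Fick's law for a fruit with an essentially astomatous skin:

    E = G × ΔPw,        ΔPw = p(T) · (1 − RH/100) / P,
    p(T) = 610.7 · exp(17.4·T / (239 + T))   [Pa]

where `E` (mmol cm⁻² h⁻¹) is the molar water flux per unit skin area, `G` the
skin conductance (same units), and `ΔPw` the dimensionless mol-fraction
vapour difference between the saturated fruit interior and the air. Because
the skin has no active stomata, `G` does not cycle diurnally but declines
developmentally; the package estimates that decline as a power law in days
after full bloom (τ):

    G′(τ) = α · τ^β

by log–log OLS, with BCa bootstrap confidence intervals from 80 %-sized
resamples drawn with replacement. A 12-regression screen (inferred `G` vs
windspeed and vs solar radiation, per campaign day) checks that neither a
boundary-layer nor a radiative-heating extension is needed. Finally
`E′ = G′(τ)·ΔPw` is evaluated on a 15-min grid over the season and summed
into cumulative transpiration per unit skin area — a growing-degree-day-style
quantity that tracks the period over which the fruit imports most of its
calcium.

A synthetic-data module generates diurnally cycling weather and replicated
weighing campaigns from the model's own forward law with known truth, so the
entire pipeline is testable end to end with no field data.

## Worked example

```r
library(kiwitrans)

weather  <- generate_weather(weather_scenario(seed = 42), cadence = 60)
campaign <- generate_campaign(campaign_scenario(seed = 7), weather)

obs   <- build_conductance_dataset(weighings_to_fluxes(campaign$weighings),
                                   weather)
model <- fit_seasonal_model_ci(obs, n_boot = 100, seed = 1)
model
#> Seasonal skin-conductance model G'(tau) = alpha * tau^beta
#>   alpha = 1.942e+04  beta = -1.985  (n = 864, adj R2 = 0.970)
#>   95% CI alpha: [1.78e+04, 2.258e+04]  beta: [-2.023, -1.964]
#>   fitted tau range: 23 to 141 days after full bloom

id <- identify_drivers(obs)
sprintf("P values in [%.3f, %.3f]: %s", id$min_p, id$max_p, id$conclusion)
#> "P values in [0.491, 0.987]: no significant driver effect:
#>  E = G * dPw accepted unextended"

series <- predict_series(model, weather, full_bloom = "2006-05-23",
                         step_minutes = 15)
tail(series$cum, 1)   # season total, mmol per cm2 of skin
#> 491.1  (over 13440 15-min grid points, days 10-150 after full bloom)

d <- obs[obs$included, ]
compare_predictions(predict_E(model, d$tau_days, d$T_C, d$RH_pct), d$E)
#> Predicted vs measured transpiration (log-log OLS, n = 864):
#>   E' = 0.9339 * E^0.9756   (R2 = 0.977 on the log scale)
```

Reading the numbers: this synthetic campaign was generated with
`G = 13400·τ^−1.90` plus fruit-to-fruit scatter (log-SD 0.2, six fruits per
day) and 1-mg balance noise. The fitted exponent −1.985 sits within the
day-level sampling noise that six replicate fruits imply (the fitted curve
and truth differ by < 10 % over the observed τ range); the comparison
regression — predictions against the very measurements the model was fitted
to — has slope ≈ 0.98 and R² ≈ 0.98 on the log scale, i.e. the single
seasonal conductance curve plus weather explains almost all the variance in
864 hourly flux measurements. The identification screen finds no windspeed
or radiation effect, as the generator contains none.

The same pipeline runs from the command line:

```sh
Rscript -e 'kiwitrans::kiwitrans_cli()' run-all --out-dir out --seed 1
```

(subcommands: `simulate-weather`, `simulate-campaign`, `estimate`, `fit`,
`identify`, `predict`/`cumulate`, `compare`, `run-all`; see
`?kiwitrans_cli`).

## More

The methods vignette (`vignettes/kiwifruit-transpiration.Rmd`) documents the
model assumptions, the resampling scheme, the screen's calibration caveats on
clustered data, all numerical conventions, and what a green synthetic test
does and does not establish.
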