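Package: kiwitrans
Title: Fick's-Law Modelling of Kiwifruit Transpiration from Weather Data
Version: 0.1.0
Authors@R:
    person("Pantanello", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to model water loss from developing kiwifruit berries as a
    molar flux driven by the water-vapour mol-fraction difference between the
    fruit interior and ambient air (Fick's law, E = G * dPw). The package
    inverts hourly gravimetric weighing campaigns against weather-station
    records to infer fruit skin conductance, fits and bootstrap-validates a
    power-law model of the seasonal conductance decline (G' = alpha * tau^beta),
    screens windspeed and solar-radiation extensions for necessity via
    per-period slope regressions, and predicts instantaneous and cumulative
    fruit transpiration over a full growing season from temperature and
    relative-humidity time series. A synthetic-data module generates diurnally
    cycling weather and replicated fruit weighing campaigns with known
    conductance truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
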