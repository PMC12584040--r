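Package: woodsim
Title: Global Wood Demand, Forest Management and Harvest Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds country-level wood commodity balances (apparent
    consumption and trade-based prices) from production and trade
    statistics, fits an income- and price-dependent demand system for
    industrial roundwood and wood fuel, emulates stand-age yield tables
    and fits annualised harvest curves of forest management intensity,
    selects least-cost combinations of timber-forest area and management
    intensity per country, clears a single global wood market with an
    endogenous price index, runs stochastic scenario ensembles to 2100,
    and attributes harvest change to area, intensity and potential-yield
    factors. A synthetic-world generator provides all inputs so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
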