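Package: maizegap
Title: Water-Driven Maize Yield Gap Simulation with an Adaptive Growing Season
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimal water-driven crop simulator for European grain maize
    with growing-degree-day phenology and a temperature-dependent sowing
    date, run under three management regimes (actual, water-limited,
    potential) to produce yields, yield gaps (YGw, YGp), water productivity,
    suitability maps and crop-failure counts for a baseline and warmed
    climate scenarios. Includes a stochastic daily weather generator
    (seasonal temperature cycle with AR(1) anomalies, two-state Markov
    precipitation, latitude-dependent radiation) and small multi-member
    climate ensembles, FAO-56 Penman-Monteith reference evapotranspiration,
    a single-bucket root-zone water balance with canopy-cover dynamics and
    normalized-water-productivity biomass accumulation, soil-fertility
    stress calibration to a target relative biomass, and ensemble-median
    spatial aggregation with cycle-completion masking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
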