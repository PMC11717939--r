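Package: mclsim
Title: Integrated Mixed Crop-Livestock System Simulator for Sahelian and
    Sudanian West Africa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Daily-time-step simulator of smallholder mixed crop-livestock
    farming systems in the West African Sahelian and Sudanian savanna zones.
    Couples a radiation-use-efficiency crop growth model (maize, millet,
    sorghum) with thermal-time phenology and rainfall-triggered sowing, an
    annual/perennial grassland model, a multi-layer tipping-bucket soil
    water balance with a mineral nitrogen pool, a six-class livestock
    demographic model with feed-energy stress, concentrate purchase and
    sell-out management, and evaluation statistics including a standardized
    water stress index. Includes a stochastic weather generator for the two
    zones and climate-change scenario deltas, so the whole system runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
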