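Package: cropstress
Title: Factorial Decomposition of Crop-Yield Variability into Climate Stress Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A switchable-stress, daily-timestep generic crop simulator (thermal-time
    phenology, radiation-use-efficiency growth, soil-water bucket, air- and
    canopy-temperature heat stress, CO2 responses for C3 and C4 cereals) together
    with the full experimental protocol around it: stochastic weather and soil
    generators, enhanced delta-change climate scenarios, a treatment x CO2 x
    scenario x model factorial runner, production-area-weighted yield aggregation,
    decomposition of yield losses into mean-temperature, drought and heat drivers,
    skill evaluation against de-trended yield statistics, and variance-based
    (main/total effect) uncertainty decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
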