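Package: sorghumsim
Title: Sorghum Growth Simulation and Sowing-Strategy Risk Analysis for
    the Ethiopian Dry Lowlands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A daily-time-step sorghum growth and water-balance simulator
    parameterized for two contrasting Ethiopian genotypes: Meko, an
    early-maturing short improved variety, and Jigurti, a late-maturing
    tall landrace. Implements field soil-characterization arithmetic
    (bulk density, drained upper limit, crop lower limit, plant
    available water capacity), thermal-time phenology with
    phase-specific cardinal temperatures, bell-shaped individual
    leaf-area profiles driven by total leaf number, a layered
    soil-water bucket with supply/demand stress, radiation-use-efficiency
    biomass accumulation with grain-number determination and stem
    translocation, a stochastic daily weather generator for unimodal and
    bimodal dry-lowland rainfall climates, and a paired long-term
    simulation experiment contrasting early sowing of late-maturing
    landraces with late sowing of early-maturing varieties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
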