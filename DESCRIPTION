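Package: forestcarbon
Title: Forest Carbon Sink Projection from Growth Models and Habitat Suitability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Projects forest aboveground biomass (AGB) and carbon sequestration
    under future climate scenarios by combining biomass-age growth curves
    (Michaelis-Menten, monomolecular, logistic) augmented with mean annual
    temperature and precipitation covariates, a CO2-fertilization ratio derived
    from vegetation-carbon responses to CO2 concentration, and habitat-suitability
    driven forest dynamics. Implements fusion of multiple land-cover and
    stand-age map products into baseline maps, per-pixel projection under a
    nature scenario (forests remain, are replaced by the most suitable other
    type, or are lost) and an afforestation scenario (planting to meet policy
    area targets, allocated at random over suitable land and averaged over
    replicates), and summary metrics (total AGB, sequestration rate, area-loss
    and structural-change rates). A synthetic-world generator produces gridded
    worlds with known ground truth so the whole pipeline is testable without
    external rasters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
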