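Package: phytoRSI
Title: Resource Supply, Temperature and the Growth of Marine Phytoplankton
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives upper-ocean hydrographic quantities (EOS-80 sigma-t,
    density-criterion mixed-layer depth, 1% light euphotic depth, nitracline
    interpolation) from CTD-style depth profiles, combines them into a
    resource supply index that summarises nutrient and light availability,
    and analyses the large-scale covariation of phytoplankton biomass,
    primary production and biomass-specific growth with reduced major-axis
    regression, bootstrap confidence intervals and rank-based group tests.
    Includes a synthetic station generator calibrated to published regional
    summary tables so the full pipeline can be exercised against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
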