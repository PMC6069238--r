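Package: dustintake
Title: Probabilistic Daily-Intake Estimation for Non-Dietary Ingestion of
    Insecticide Residues in House Dust and Soil
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo estimation of young children's daily intake of
    insecticides (chlorpyrifos, cypermethrin) through non-dietary ingestion
    of indoor dust and outdoor soil. Fits lognormal input distributions from
    published summary statistics (arithmetic moments, percentile tables, or
    left-censored concentration samples with half-LOD substitution),
    simulates the intake equation IR x C x CF / BW with replicate-based 95%
    confidence intervals on the percentiles of intake expressed as percent
    of the Acceptable Daily Intake, performs contribution-to-variance
    sensitivity analysis, and compares non-dietary against published dietary
    exposure percentiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
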