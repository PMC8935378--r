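Package: cassavaNPK
Title: Simulation of Nutrient-Limited Cassava Growth Under Combined N, P and K Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Daily radiation-use-efficiency simulation of cassava growth under
    combined nitrogen, phosphorus and potassium limitation. Tracks soil
    nutrient pools with first-order fertilizer release and water-limited
    recovery, converts crop demand and soil supply into nutrient equivalents
    (QUEFTS-style) to couple N, P and K uptake, derives per-nutrient nutrition
    indices and a combined saturating (Monod-type) stress index that reduces
    growth, and partitions dry matter over leaves, stems, storage roots and
    fine roots along thermal time. Includes a tipping-bucket water balance, a
    synthetic tropical weather generator, an NPK omission/factorial treatment
    battery, and calibration (grid search plus simplex) and evaluation (RMSEP,
    R-squared, slope) tools with a parameter-recovery harness on synthetic
    observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
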