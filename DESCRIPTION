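Package: tracerpart
Title: Source Partitioning of Plant Phosphorus Uptake from 32P Isotope Dilution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pot experiments in which soil phosphorus is labeled with
    carrier-free 32P to partition shoot P uptake into soil-, seed-, and
    fertilizer-derived fractions. Provides decay correction, specific activity
    and L-value calculations, the isotope-dilution partitioning chain (Pdff,
    fertilizer P recovery, agronomic effectiveness), fertilizer dose budgeting
    with heavy-metal compliance checks, NaOH-trap back-titration soil
    respiration series, one-way ANOVA with Student-Newman-Keuls letter
    groupings, and a calibrated synthetic pot-experiment and incubation
    generator with known ground truth for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
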