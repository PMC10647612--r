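Package: sweetval
Title: Validation Statistics for Targeted LC-MS/MS Quantitation of Steviol Glycosides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-laboratory validation of targeted UHPLC-ESI-MS/MS
    quantitation of steviol glycosides and related sweeteners. Implements the
    standard validation statistics (retention-time relative percent difference,
    percent relative standard deviation, Horwitz predicted RSD and HorRat,
    spike recovery, absolute matrix effect, replicate-based limits of detection
    and quantitation), external and matrix-matched linear calibration with
    back-calculation, selected-reaction-monitoring peak-to-analyte assignment
    from a transition table, steviol-equivalent conversion with lower/middle/
    upper-bound substitution of left-censored results, a seeded synthetic
    instrument-data generator, and a pipeline that assembles per-analyte,
    per-matrix validation reports with pass/fail verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
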