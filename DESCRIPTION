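Package: exportome
Title: Nucleocytoplasmic Partitioning and RanGTP-Dependent CRM1 Cargo
    Classification from Intensity-Based Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for spike-in-calibrated absolute protein quantitation in
    dissected oocyte fractions and for scoring RanGTP-dependent CRM1 binders
    from affinity-chromatography intensity tables. Implements identification
    filters, allelic proteoform merging, UPS2-style calibration regression,
    volume-based conversion to molar concentrations, nuclear-to-cytoplasmic
    (N:C) partition coefficients, molar-fraction/enrichment/RanGTP-stimulation
    scoring with conservative baseline imputation, and rule-based cargo
    categories. A synthetic-data generator simulates both experiments with
    known ground truth so every downstream stage is testable without raw
    mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
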