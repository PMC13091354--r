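Package: kinomechip
Title: Kinome Peptide Microarray Activity Profiling and Drug-Response Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of real-time kinase-activity profiling on
    PTK/STK peptide microarrays (PamChip-style assays). Generates synthetic
    multi-cycle, multi-exposure spot intensities with known kinase-activity
    ground truth including drug inhibition; quantifies substrate signals via
    exposure-slope regression with saturation handling; computes per-substrate
    log fold changes; infers upstream kinase activity with sampling-null
    Z-scores and a two-component specificity/significance ranking; and scores
    per-patient drug responses (PerMed percent-change scores) with
    on-target/off-target and non-responder calls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
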