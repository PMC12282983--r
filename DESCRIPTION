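Package: icubench
Title: Federated ICU Benchmarking with APACHE II on OMOP CDM Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking intensive care units across quality
    registries whose data are standardized to the OMOP Common Data Model.
    Reads and validates an OMOP CDM table subset, extracts first-24-hour
    worst physiology per admission through per-source concept/table
    configuration files, computes APACHE II severity scores and predicted
    ICU mortality risks, handles missing data either by normal-range
    zero-weight fill or by predictive-mean-matching multiple imputation
    pooled with Rubin's rules, and reports registry-level standardized
    mortality ratios with exact Poisson funnel-plot control limits. A
    seeded synthetic OMOP data generator with known ground truth emulates
    two registries' structural dialects so the full pipeline is testable
    without access-controlled registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    grDevices,
    tools,
    jsonlite,
    purrr,
    readr,
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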