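Package: oncofed
Title: Federated Analysis Pipeline for Oncological Basic Dataset Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A modular pipeline that turns oncological basic dataset (oBDS)
    XML exports from hospital tumor documentation systems into FHIR-style
    Patient/Condition resources, pseudonymizes them with configurable
    deidentification rules, flattens them into per-site analysis tables with
    ICD-10 entity grouping, and answers epidemiological questions through
    disclosure-controlled federated aggregation across sites. Includes a
    synthetic-data generator for per-site entity-by-gender count structures,
    a mean-absolute-percentage-error validation metric against gold-standard
    count tables, and registry-comparison reports. Patient-level rows never
    leave the site aggregation step; only small-cell-suppressed aggregates
    are combined.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    xml2,
    yaml,
    jsonlite,
    openssl,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
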