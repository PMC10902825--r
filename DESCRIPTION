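Package: echoclean
Title: Rule-Based Cleaning of Semi-Structured Echocardiography Report Exports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts delimited-text exports of echocardiography (cardiac
    ultrasound) studies from a PACS database into a clean, analysable,
    de-identified dataset. Provides declarative phrase rules that grade
    free-text valve and ventricular descriptions into ordinal severity
    levels, numeric recoding rules (plausibility bounds, range averaging,
    method hierarchies, unit-anchored extraction from free text),
    pseudonymisation through a separately stored lookup table, derived
    clinical variables including a guideline diastolic-function decision
    tree, and a validation workflow based on percent agreement and
    Cohen's kappa against a gold standard. A synthetic report generator
    with hidden ground-truth labels makes every stage testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
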