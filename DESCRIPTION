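Package: paynet
Title: Drug Company Payments to General Practices: Linkage, Concentration
    and Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing industry transfer-of-value disclosures to
    English general practices: record linkage of free-text recipient names
    to practice codes with exclusion accounting, VAT normalisation of
    disclosed amounts, payment-concentration descriptives (top-k donor
    shares, per-company and per-practice profiles), stratified Wilcoxon
    rank-sum comparisons across practice characteristics, and thresholded
    valued company networks built from shared recipient practices. A
    synthetic-data generator calibrated to the published 2015 summary
    statistics makes every stage runnable and testable without the
    original extract.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
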