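Package: returnflow
Title: Residence Classification and Markov Projection of Return Migration
    for Hong Kong-Born Children of Mainland Parents
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies the yearly "returned" residence status of Hong
    Kong-born children of Mainland Chinese parents from raw border-crossing
    event logs (31 nights within a calendar half-year), tabulates
    noncumulative return rates by birth cohort, child type and parental
    education, estimates cohort-specific two-state Markov transition
    probabilities from the resulting status panel by maximum likelihood,
    and projects future return rates and aggregate returnee counts.
    A seeded synthetic-microdata generator emulates the structure of
    confidential immigration movement records so that every stage of the
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
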