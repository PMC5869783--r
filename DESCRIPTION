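Package: htcascade
Title: Effective Coverage of Hypertension Screening Care Cascades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to measure the effective coverage of population
    hypertension screening from individual-level administrative health
    records. Provides a validated six-file record schema for person,
    screening, service, diagnosis, registry and follow-up events;
    eligibility determination for the screening target population; blood
    pressure subgroup classification (normotension, pre-hypertension,
    suspected hypertension); per-subgroup effectiveness criteria with
    configurable confirmation and treatment windows; individual effective
    coverage as the product of quality and utilization over the need
    population; and aggregation into care-cascade tables with provincial
    and national summaries. A synthetic cohort generator with exact-quota
    and stochastic modes emulates the structure of restricted national
    claims data so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
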