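Package: suddenshifts
Title: Detection and Analysis of Sudden Gains in Session-by-Session
    Therapy Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies sudden gains and sudden losses in routinely collected
    session-by-session psychological-therapy measures using the three
    Tang-DeRubeis criteria: a large absolute between-session change calibrated
    by the Jacobson-Truax reliable change index, a change of at least 25% of
    the pregain score, and statistical stability of the surrounding sessions
    assessed with a pooled two-sample t-test whose critical value adapts to
    missing observations. Tracks reversals of gains, aggregates cohort-level
    summaries (occurrence, modal session, magnitude, multiples, reversals),
    and estimates adjusted odds ratios for predictors of gains and adjusted
    mean differences for end-of-treatment and follow-up outcomes. Includes a
    synthetic cohort generator with planted step-change gains, covariate-driven
    gain probability and missing-completely-at-random gaps so the full
    pipeline is testable without access to trial data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
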