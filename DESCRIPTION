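Package: smartrand
Title: Automated Double Randomization for Sequential Multiple Assignment
    Randomized Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained engine for automated two-stage (double)
    randomization in Sequential Multiple Assignment Randomized Trials
    (SMARTs). Implements daily report-based eligibility queries as
    conjunctive rule sets, permuted-block allocation-table generation,
    first-stage rotation assignment (assign from the top, move the row to
    the bottom), stratified second-stage assignment by sequential scan on
    first-arm and tailoring-variable status, weekday entry gating, an
    append-only assignment audit log with exact replay, a synthetic SMART
    cohort simulator with a realistic anomaly taxonomy (dropouts, missing
    tailoring data, manual overrides), CONSORT-style participant-flow
    accounting, and a normal-approximation power helper for two-sample
    proportions. A command-line interface exposes table generation,
    eligibility reports, batch randomization, simulation and flow reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
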