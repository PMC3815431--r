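Package: mprmonitor
Title: Medication Possession Ratio Monitoring and Adherence Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes running medication possession ratio (MPR) trajectories
    from prescription fulfillment histories, detects refill gaps with supply
    carryover, flags current non-adherence (30-day gap check and MPR < 0.8
    check), and applies configurable drug-class-specific logistic models of
    age and early MPR to predict poor adherence one year after the first
    fill. Emits per-medication clinician-style assessments (red/yellow/green
    flags) as tidy tibbles, JSON/CSV/HTML reports and plot payloads, and
    ships a seeded synthetic fulfillment generator with analytic ground
    truth for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
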