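Package: mcpcea
Title: Markov Cohort Cost-Effectiveness Model for Screening and Minimal
    Contact Psychotherapy in Sub-Threshold Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-week-cycle Markov cohort model of sub-threshold
    depression, major depressive episodes and recovery, with
    duration-dependent recovery and relapse hazards expressed through
    tunnel states.  Computes disability-adjusted life years (DALYs) and
    costs from health-care and societal perspectives under differential
    discounting, models an opportunistic screening cascade in primary
    care, and propagates parameter uncertainty by probabilistic
    sensitivity analysis to produce incremental cost-effectiveness
    ratios, cost-effectiveness planes and acceptability curves.
    Includes an individual-level microsimulation oracle for validating
    the cohort engine and a synthetic-data generator for recovery and
    relapse probability curves and pseudo-trial event counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
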