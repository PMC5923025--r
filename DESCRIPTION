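Package: triagesim
Title: Simulation and Evaluation of Primary Mass-Casualty-Incident Triage Performance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying primary triage quality in mass casualty
    incidents (MCI). Provides a data-driven decision-tree engine for
    START-family triage algorithms (the shipped configuration follows the
    Amberg-Schwandorf Algorithm for Primary Triage, ASAV), a synthetic
    cohort simulator emulating patient vignette pools, two-person triage
    teams, time-dependent provider skill decay and re-training, and the
    complete evaluation layer used in longitudinal triage assessment
    studies: triage error taxonomy, accuracy, sensitivity and specificity
    for red patients, (critical) over- and under-triage rates, a ten-item
    checklist performance score with pass rate, category-weighted triage
    times, team qualification probability, and the associated statistical
    comparisons (ANOVA with Bonferroni post-hoc tests, paired t-test,
    Wilcoxon signed-rank test with Pratt zero handling, Shapiro-Wilk).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
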