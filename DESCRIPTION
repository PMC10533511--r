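Package: faor
Title: Fetal Abdominal Overgrowth Ratios and Perinatal Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying fetal abdominal obesity (FAO) in pregnancy
    cohorts with normal glucose tolerance. Converts fetal biometry
    (biparietal diameter, abdominal circumference, femur length) to
    ultrasound-estimated gestational ages by inverting monotone growth-chart
    reference curves, computes fetal abdominal overgrowth ratios (FAORs) and
    classifies FAO against empirical 90th-percentile cutoffs, implements the
    two-step 50-g glucose challenge / 100-g oral glucose tolerance screening
    cascade that defines a normal-glucose-tolerance cohort, assigns maternal
    age-by-BMI subgroups, and runs the downstream statistical battery
    (pairwise t and proportion tests with Bonferroni correction, crude and
    model-based odds ratios, correlations, and linear models of FAORs on
    clinical factors). A synthetic-cohort generator with planted,
    retrievable effect sizes makes every pipeline stage testable without
    access to patient-level data.
License: MIT + file LICENSE
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
    readr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
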