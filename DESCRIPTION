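Package: mssval
Title: Murine Sepsis Score Validation and Cohort Simulation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formal implementation of the Murine Sepsis Score (MSS), a
    seven-item ordinal rubric (0-4 per item, total 0-28) for grading disease
    severity in mouse models of fecal-induced peritonitis, together with the
    humane-endpoint euthanasia rule and the two-hourly/hourly monitoring
    schedule. Includes a calibrated stochastic simulator of multi-dose
    peritonitis cohorts scored by two raters, and from-first-principles
    validation statistics: Cronbach's alpha, two-way random-effects
    intraclass correlation ICC(2,1) with F-based confidence intervals,
    Friedman's test, empirical ROC curves with trapezoid AUC and
    Hanley-McNeil intervals, Youden-index cutoff selection with exact
    Clopper-Pearson operating-point intervals, Kaplan-Meier survival by dose
    group, score-conditional mortality-window statistics, and Spearman rank
    correlation with exact small-sample permutation p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    survival
Config/testthat/edition: 3
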