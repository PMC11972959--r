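Package: bidirmr
Title: Bidirectional Mendelian Randomization with Risk-Score Trajectories
    and Survival Linkage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for bidirectional Mendelian randomization
    between systolic blood pressure and fasting blood sugar: variant QC
    (call rate, exact Hardy-Weinberg test, minor allele frequency),
    per-SNP GWAS, greedy LD clumping, weighted genetic risk scores,
    two-stage least squares with weak-instrument and Wu-Hausman
    diagnostics, and summary-statistic estimators (IVW, simple and
    weighted median, MR-Egger) with leave-one-out pleiotropy screening.
    Downstream stages build genetically predicted phenotype series,
    fit group-based trajectory models by EM with BIC selection, and link
    trajectory groups to incident disease through person-year accounting,
    exact Poisson incidence intervals, and Efron-tie Cox regression.
    A synthetic cohort generator with a bidirectional structural model
    emulates the biennial middle-aged cohort design the methods assume,
    so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    mclust,
    withr
Config/testthat/edition: 3
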