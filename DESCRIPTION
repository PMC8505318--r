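Package: ppcsrna
Title: Salivary Small RNA Prognosis of Persistent Post-Concussion Symptoms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and machine-learning analysis of salivary small
    non-coding RNA (miRNA, snoRNA, piRNA) profiles for prognosis of
    persistent post-concussion symptoms (PPCS) after mild traumatic brain
    injury. Provides a longitudinal cohort and count-matrix simulator,
    piRNA sequence clustering into wiRNA clusters, abundance filtering
    with total-sum-scaling normalisation and inverse hyperbolic sine
    transformation, negative-binomial Wald differential expression with
    Benjamini-Hochberg correction, Pearson association scans, PCSS symptom
    scoring, a modified Zemek 12-point clinical risk score, minimal
    detectable change classification, multi-stream feature selection with
    multifold consensus and recursive feature elimination, radial-kernel
    support vector machine and random-forest classifiers with
    evaluation-set probability-threshold tuning, DeLong ROC inference,
    and Hanley-McNeil AUC power calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    Biostrings,
    glmnet,
    ranger,
    nnet,
    e1071,
    xgboost,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    DESeq2,
    S4Vectors
Config/testthat/edition: 3
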