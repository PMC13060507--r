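Package: fluctex
Title: Resting-State EEG Dominant-Frequency Features of Cognitive
    Fluctuations in Lewy Body Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts the quantitative resting-state EEG features used to
    characterize cognitive fluctuations across the Lewy body disease
    spectrum: per-epoch dominant frequency (DF), dominant-frequency
    variability (DFV), dominant-frequency prevalence (DFP) over a
    delta/theta/pre-alpha/alpha/beta band scheme, and individual alpha
    peak frequency (IAF), computed per channel and averaged over
    anterior, temporal, posterior and global derivations. Includes an
    EDF reader/writer for standard 10-20 montages, the group-comparison
    layer (median/IQR summaries, Mann-Whitney U with effect size r,
    Benjamini-Hochberg FDR), covariate-adjusted logistic models,
    elastic-net and forward-AIC classifiers with ROC/AUC, and a
    synthetic EEG cohort generator (pink-noise background with
    epoch-switching band oscillators) so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    glmnet,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
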