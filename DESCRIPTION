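Package: methAgeQR
Title: Cross-Platform Forensic Age Prediction from CpG Methylation with
    Quantile Regression
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating forensic age-prediction
    models from targeted CpG methylation beta-values measured on different
    detection technologies (EpiTYPER, pyrosequencing, MiSeq, SNaPshot-style
    single-base extension). Implements multivariate linear quantile
    regression by exact pinball-loss minimisation (q10/q50/q90 prediction
    intervals), Bland-Altman inter-technology agreement with an a-priori
    limit of agreement, per-CpG z-score harmonisation for
    platform-independent prediction, replicate-concordance and cluster
    handling for beta-value tables, k-fold cross-validation with the
    field's accuracy metrics (median absolute error, RMSE, %CP+/-5,
    %CP+/-PI), and a synthetic-cohort generator emulating age trajectories,
    biological noise and platform measurement bias.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Regression, BatchEffect
RoxygenNote: 7.3.3
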