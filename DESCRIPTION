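Package: TRSig
Title: Tumor-Reactive T Cell Signature Derivation, Scoring and Survival Evaluation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives tumor-reactive CD8+ T cell gene signatures from
    cluster-labeled single-cell expression via rank-sum marker testing and
    one-vs-rest ROC-AUC ranking; scores bulk samples and single cells with
    five single-sample gene-set statistics (kernel-CDF KS, rank-weighted KS,
    combined z, first singular vector, ranking recovery); refines signatures
    by backward elimination under a univariate Cox AIC objective; quantifies
    TCR clonal expansion and downsampling-rarefied Shannon diversity; and
    evaluates prognostic and immunotherapy-response value with Kaplan-Meier,
    log-rank, Cox proportional hazards, Harrell concordance, time-dependent
    ROC AUC and restricted mean survival time ratios. Ships a seeded
    synthetic-data generator emulating the assumed statistical structure so
    the whole workflow is testable without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    survival,
    Matrix,
    fgsea,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TRSig-package.R'
    'ranksum.R'
    'cohort.R'
    'derivation.R'
    'gating.R'
    'io.R'
    'survival.R'
    'scoring.R'
    'refine.R'
    'tcr.R'
    'synthetic.R'
    'pipeline.R'
    'reexports.R'
    'utils.R'
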