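Package: regulonSurv
Title: Risk Scoring of Transcription-Factor lncRNA Regulons in Survival
    Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks transcription factors by the prognostic value of the long
    non-coding RNAs they regulate. Candidate TF-lncRNA binding pairs are
    filtered by expression correlation into regulons; each regulon is scored
    per patient as a linear combination of lncRNA expression weighted by
    univariate Cox coefficients; patients are split at the median risk score
    and compared by Kaplan-Meier and log-rank analysis. Includes independent
    cohort validation by refitting or by z-score cut-point transfer, clinical
    stratification and multivariate adjustment, time-dependent ROC comparison
    of signatures, cross-cohort risk-direction consistency filtering, and a
    multi-cohort proportional-hazards simulator so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Survival, GeneExpression, GeneRegulation, Transcriptomics
RoxygenNote: 7.3.3
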