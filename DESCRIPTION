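Package: scsnv
Title: Ensemble Prediction of Splice-Altering Single Nucleotide Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts whether single nucleotide variants within splicing
    consensus regions (scSNVs; donor -3..+8, acceptor -12..+2) alter
    pre-mRNA splicing. Provides self-contained donor/acceptor splice-site
    scoring engines (a 0-100 normalized position weight matrix model and a
    maximum-entropy model with low-order adjacent marginal constraints),
    transforms wild-type/mutant score pairs into relative and absolute
    score variations with a missing-score rule and tool screening, trains
    gentle/real boosting and random-forest ensemble classifiers emitting
    interpretable splice-altering probabilities (ada_score, rf_score),
    evaluates them with 10-fold cross-validated ROC analysis including
    accuracy-maximizing cutoffs and cross-validated paired t-tests, applies
    trend and chi-squared enrichment statistics to recurrence and gene-class
    contingency tables, enumerates all potential scSNVs from gene models
    into a tab-delimited score database with VCF annotation, and generates
    calibrated synthetic inputs for every step.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    randomForest,
    rpart,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
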