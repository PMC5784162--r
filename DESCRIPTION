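Package: cassavaGS
Title: Two-Stage GWAS and Genomic Prediction for Cassava Brown Streak Disease
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A two-stage genomic analysis pipeline for cassava brown streak
    disease (CBSD) resistance in multi-location breeding trials. Stage one
    fits trial-design linear mixed models (alpha-lattice and augmented
    designs) to ordinal severity scores and extracts de-regressed BLUPs,
    prediction error variances and entry-mean heritabilities. Stage two
    provides marker quality control, VanRaden genomic relationship matrices,
    SNP heritability, principal components, mixed-linear-model association
    with leave-one-chromosome-out kinship, and seven genomic prediction
    models (GBLUP, chromosome-partitioned multi-kernel GBLUP, multi-kernel
    Gaussian RKHS, BayesA, BayesB, BayesC-pi, Bayesian LASSO, and Random
    Forest) under a cross-validation harness. Companion tools detect
    Manihot glaziovii introgression segments from ancestry-informative SNPs
    by windowed majority calling and compute LD scores from adjusted r
    squared. A synthetic breeding-panel generator with known genetic
    architecture supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    lme4,
    randomForest,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
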