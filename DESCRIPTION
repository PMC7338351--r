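Package: epiboost
Title: Networks of Interacting Genetic Variants and Demographic Risk
    Factors via Gradient Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers networks of interacting single-nucleotide
    polymorphisms (SNPs) and demographic risk factors for case-control
    disease prediction. An XGBoost classifier ranks candidate features by
    split-gain importance; a greedy adaptive search over the top-ranked
    SNPs concatenated with demographic feature groups selects the subset
    maximising validation average precision; repeated stratified
    cross-validation aggregates the selected networks and their test-set
    average precision into a mean average precision (mAP). Includes a
    synthetic case-control cohort generator with known ground truth
    (logistic disease model with main effects, SNP-SNP epistasis and
    SNP-demographic interactions), polygenic risk score and fixed-feature
    baselines, precision-recall evaluation metrics, per-feature
    association tests, leave-one-feature-out importance, and SNP-to-gene
    window annotation with gene-network export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    xgboost,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
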