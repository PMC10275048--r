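Package: csfProteoGenomics
Title: Proteogenomic pQTL Mapping, Disease Integration and Proteomic Risk
    Scores for CSF Aptamer Proteomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for cerebrospinal-fluid (CSF)
    proteogenomics: quality control of aptamer-based protein measurements
    and genotype dosages, per-aptamer genome-wide linear-model scans with a
    principal-component-derived study-wide significance threshold for trans
    associations, inverse-variance fixed-effect meta-analysis with genomic
    control, greedy index-signal detection and exact stepwise conditional
    analysis, LD-based pleiotropic-region grouping, permutation enrichment of
    variant consequence categories, brain cell-type specificity, integration
    with a disease GWAS through approximate-Bayes-factor colocalization,
    two-sample Mendelian randomization and a proteome-wide association study,
    and direction-harmonized proteomic risk scores benchmarked against a
    polygenic risk score. Ships a seeded synthetic-cohort generator that
    emulates the data structure the pipeline assumes, with a ground-truth
    table for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    pROC,
    igraph,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
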