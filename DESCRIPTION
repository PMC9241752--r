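Package: dysbionet
Title: Microbiome Dysbiosis Analysis with Co-Abundance Network Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for the statistical analysis of fecal 16S
    amplicon sequence variant (ASV) tables from case-control cohorts, built
    around inflammatory bowel disease in remission. Covers rarefaction and
    coverage, alpha diversity with phylogenetic null models (NRI/NTI) and
    backward-AIC covariate models, Bray-Curtis/Jaccard/generalized UniFrac
    beta diversity with PCoA and PERMANOVA, covariate-adjusted
    negative-binomial differential abundance and indicator species analysis,
    and a SparCC co-abundance network layer with permutation-based
    centrality significance, fast-greedy module detection, and a per-subject
    module-completeness statistic associated with disease condition and
    clinical activity scores. A synthetic-cohort generator reproduces the
    statistical structure the analysis assumes, so every stage is testable
    without access to the original sequence archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    MASS,
    picante,
    stats,
    utils,
    vegan
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
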