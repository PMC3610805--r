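Package: cisxpred
Title: Genotype-Only Prediction of Gene Expression from cis-SNPs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts inter-individual gene expression differences using only
    genotype information at cis-SNPs. Implements four per-gene predictors
    (single best-SNP regression, elastic-net regression over all cis-SNPs,
    K-nearest-neighbor regression under an L1 allele-count metric, and an
    extended KNN that learns a genomic-feature-weighted distance metric by
    greedy search over feature-coefficient combinations), their combination by
    prediction averaging, three population-aware cross-validation schemes
    (Cross-Pop, Mixed-Pop, Intra-Pop), robustness statistics relating training
    and test R-squared, hypergeometric enrichment of genomic features among
    selected SNPs and feature weights with Benjamini-Hochberg FDR control, and
    a synthetic-data generator with planted cis effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    glmnet,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
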