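Package: responseQTL
Title: Bayesian Mapping of Genotype-Treatment Interactions from Paired
    Two-Condition Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects response eQTLs (genotype-by-treatment interactions)
    from paired phenotype measurements taken on the same individuals under
    two conditions, such as glucocorticoid-treated and vehicle-treated
    aliquots of the same cell line. Five competing models of association
    (null, no-interaction, treatment-only, control-only, general
    interaction) are compared per SNP with closed-form grid-prior Bayes
    factors on a difference/average decomposition that accounts for
    intra-individual correlation. A hierarchical model combines evidence
    across SNPs within each gene and across genes, estimating genome-wide
    model proportions by EM and per-gene posterior probabilities, with a
    posterior-based estimate of the false discovery rate. Also provides the
    frequentist log-fold-change association scan with permutation-based
    FDR, a population-by-treatment contrast, genetic prediction of
    between-population response differences, allelic-imbalance and
    set-overlap validation statistics, and a synthetic-data simulator with
    known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, SNP, Bayesian, GeneRegulation,
    DifferentialExpression, GenomicVariation
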