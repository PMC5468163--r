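Package: hybridclines
Title: Divergence and Introgression Outlier Analysis for Hybrid Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contrasting lineage divergence with introgression in
    hybrid zones from reduced-representation SNP data. Computes per-locus
    nucleotide diversity, Weir-Cockerham FST and absolute divergence (dxy)
    between two parental populations, flags multivariate outliers by
    Mahalanobis distance, calibrates differentiation against a neutral
    two-population isolation coalescent by posterior-predictive simulation,
    fits Bayesian genomic clines (hybrid index, cline center alpha and rate
    beta) in an admixed population by MCMC, and synthesises the two axes via
    correlations, gene-overlap resampling and candidate gene-set enrichment.
    Includes generators for synthetic parental, admixed and null-admixed
    datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
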