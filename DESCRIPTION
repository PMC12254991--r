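Package: divgwas
Title: Bivariate BayesB GWAS for Pleiotropic Regions in Divergently Selected Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian multiple-marker regression (BayesB) genome-wide association
    for two traits jointly, aimed at detecting pleiotropic genomic regions in
    populations divergently selected on one of the traits. Provides a Gibbs
    sampler with a four-state marker inclusion indicator, pedigree polygenic and
    common-litter random effects, inverse-Wishart covariance updates, 1-Mb
    sliding-window genetic-variance and genetic-correlation summaries with
    region merging, per-SNP posterior probabilities of association, genotype
    quality-control filters, an annotated whole-genome-sequencing
    allele-frequency divergence screen, and a gene-dropping simulator of
    two-line divergent selection experiments for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    data.table,
    stats,
    utils,
    methods,
    ggplot2,
    yaml,
    jsonlite,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
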