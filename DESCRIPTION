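Package: hybridcov
Title: Hybrid Genomic Prediction with Parental Phenotypic Covariates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-kernel Gaussian mixed models for predicting the
    performance of single-cross hybrids from two parental pools, with
    optional mid-parent phenotypic covariates. Builds genomic
    relationship matrices from SNP dosages, specific-combining-ability
    kernels as Kronecker sub-matrices, and Hadamard
    genotype-by-environment interaction kernels; fits the models with a
    Gibbs sampler over eigendecomposed kernels; and evaluates model
    families by untested-lines-in-tested-environments cross-validation
    compared through relative efficiency of mean squared error. Includes
    a synthetic hybrid-breeding data generator with ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    withr,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
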