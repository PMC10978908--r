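Package: umbpipe
Title: Lineage Differentiation and Flowering-Time Clines from 3'-Tag RNA-Seq
Version: 0.1.0
Authors@R: person("Umbpipe", "Developers", role = c("aut", "cre"),
    email = "umbpipe@example.org")
Description: A tested, reusable pipeline for studying lineage differentiation
    and latitudinal flowering-time clines in selfing wild wheat relatives
    genotyped by 3'-tag RNA-seq. Provides iterative pseudo-reference
    polishing (align, call homozygous SNPs, substitute, repeat to a
    SNP-count plateau), coverage-stratified genotype matrices, a
    Gibbs-sampled admixture model with Evanno delta-K cluster selection and
    Q-value lineage assignment, Weir-Cockerham F_ST, Kimura two-parameter
    neighbor-joining trees with bootstrap support, Bayesian linear mixed
    models for lineage-by-season phenotypes, probabilistic-PCA imputation,
    and climate / latitudinal cline regressions. A synthetic-data module
    generates sequences, reads, phenotypes and geo-climate tables with
    known ground truth so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
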