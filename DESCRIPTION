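Package: gpsel
Title: Genomic Prediction with GWAS-Based Pre-Selection of Sequence SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how pre-selecting trait-associated sequence
    variants improves genomic prediction in livestock populations. Provides a
    synthetic pig-like population simulator (LD-structured genotypes,
    two-generation pedigree, planted QTLs), PLINK bed/bim/fam input/output with
    quality-control filters and LD pruning, pedigree (A) and genomic (G)
    relationship matrices including leave-one-chromosome-out variants, AI-REML
    variance-component estimation with BLUP solving for one- and two-component
    models, mixed-linear-model association scans with Bonferroni thresholds and
    QTL-region calling, a Gibbs sampler for a four-distribution normal-mixture
    SNP-effect model, and a five-fold cross-validation harness comparing
    pedigree, GBLUP, and Bayesian-mixture prediction approaches with and
    without fold-internal pre-selection of significant SNPs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
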