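Package: badgerabc
Title: Demographic Inference of Badger Introductions from Britain into Ireland
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dating and characterising the introduction of British
    badgers (Meles meles) into Ireland from multi-locus microsatellite and
    mitochondrial control-region data.  Implements a backwards-in-time
    coalescent simulator for microsatellite loci under a generalized stepwise
    mutation model with two competing demographic scenarios (divergence versus
    admixture), approximate Bayesian computation for scenario choice (weighted
    logistic regression) and parameter estimation (local-linear regression
    adjustment), descriptive population-genetic statistics (allele numbers,
    heterozygosities, Weir-Cockerham F-statistics, Jost's D, Garza-Williamson
    M-ratio, delta-mu-squared), mitochondrial haplotype assignment against a
    reference catalogue, Evanno delta-K post-processing of Bayesian clustering
    output, and a synthetic-data generator reproducing the sampling design of
    the source study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
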