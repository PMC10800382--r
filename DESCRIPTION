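Package: pleioscan
Title: Shared Genetic Architecture and Pleiotropic Gene Discovery from
    GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture shared by
    related complex traits using only genome-wide association summary
    statistics and a reference genotype panel.  Implements univariate,
    bivariate and stratified LD score regression with block-jackknife
    standard errors; a four-component bivariate Gaussian mixture model of
    causal effects that quantifies polygenic overlap (unique and shared
    causal variants, mixture-implied genetic correlation) via
    characteristic-function likelihoods; conditional Q-Q diagnostics of
    cross-trait enrichment; and gene-based adaptive sum-of-powered-score
    tests (SPUs, aSPUs, MTSPUsSet, MTaSPUsSet) with matrix-normal
    Monte-Carlo null distributions and staged replicate escalation for
    genome scans that classify pleiotropic genes.  A fully parameterised
    synthetic-data generator with recorded ground truth supports
    calibration and power studies of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
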