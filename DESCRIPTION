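Package: epiQTL
Title: Whole-Genome Epistatic QTL Mapping with the Empirical Bayes Lasso
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Whole-genome quantitative trait locus (QTL) mapping for
    biparental populations (recombinant inbred lines and immortalized F2
    crosses) that scores additive and dominance main effects of every
    marker bin together with all pairwise epistatic interactions. A sparse
    empirical-Bayes Lasso solver (normal-exponential-gamma hierarchical
    shrinkage, coordinate ascent on the penalized marginal likelihood)
    selects effects among millions of candidates without ever storing the
    full design matrix. Includes three-step five-fold cross-validation
    with the one-standard-error rule for hyperparameter selection,
    t-based significance testing from the posterior covariance,
    variance-explained decomposition with an OLS refit, QTL grouping and
    gene-proximity annotation, and a synthetic immortalized-F2 population
    generator with power/FDR recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
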