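Package: covmatch
Title: Covariate-Matched Null Gene Sets for Enrichment Analysis
Version: 0.1.0
Authors@R: person("Rebecca", "Ouwenga-Lab Tools", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds covariate-matched null distributions for gene-set overlap
    tests. Given a per-gene table of expression, coding-sequence length,
    transcript length and CLIP tag counts, the package assigns each background
    gene a sampling probability equal to the ratio of a kernel density
    estimate fit on a target set's covariates to one fit on the whole
    universe, draws replicate gene sets without replacement that match the
    target's expression and/or length distribution, tests each against
    candidate gene lists with the exact right-tail Fisher test, and fits
    linear models of log2 CLIP tag depth on transcript abundance and length.
    A synthetic-data generator with known covariance structure makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
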