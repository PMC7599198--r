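Package: parafacov
Title: Structural Parafac Models for Three-Way Covariance Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Confirmatory factor analysis of variables-by-occasions covariance
    matrices with Khatri-Rao structured loadings (the structural Parafac
    model). Supports scale-invariant variants via a positive diagonal scaling
    matrix, correlated specific factors (within-occasion block-diagonal or
    within-variable banded structures), maximum likelihood, generalized and
    ordinary least squares discrepancy estimation with multi-start Newton-type
    optimization, chi-square goodness-of-fit tests, AIC/BIC model comparison
    tables, runnable checkers for Kruskal-type factor uniqueness conditions,
    and seeded generation of identifiable synthetic models for recovery
    experiments. Ships the classic multitrait-multimethod correlation matrix
    of Bentler and McClain as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
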