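Package: twinpgs
Title: Twin Variance Decomposition and Polygenic Score Analysis of
    University Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood twin modelling and polygenic score
    prediction for university-success phenotypes. Fits univariate ACE
    models and their nested submodels, liability threshold models for
    binary traits via tetrachoric correlations, and multivariate
    correlated-factors, common-pathway and independent-pathway models,
    with likelihood-ratio model comparison and profile-likelihood
    confidence intervals. Includes clumping-and-thresholding polygenic
    scoring across a high-resolution p-value grid with principal
    component correction and Nagelkerke pseudo-R-squared reporting, a
    rank-based inverse-normal (van der Waerden) preprocessing pipeline,
    and a synthetic twin-cohort and genotype-panel generator so that
    every stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
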