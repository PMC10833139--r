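Package: mvintegrate
Title: Multiview Data Integration with Sparse Canonical Correlation and
    Integrative Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("mvintegrate", "developers", email = "mvintegrate@example.org",
           role = c("aut", "cre"))
Description: A workflow for integrating two or more omics views measured on
    the same samples: per-view preprocessing and supervised/unsupervised
    feature filtering with multiplicity adjustment, sparse canonical
    correlation analysis via soft-thresholded (SELP) updates with
    cross-validated tuning, outcome prediction from canonical variates
    (gaussian, binomial, Poisson and Cox families), sparse integrative
    discriminant analysis for two or more views with an optional
    graph-Laplacian structured variant, visualization tables (volcano, UMAP,
    variable importance, discriminant, correlation, relevance network,
    loadings and biplots), synthetic-data generators with analytically known
    ground truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival,
    uwot
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
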