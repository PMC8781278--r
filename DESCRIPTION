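Package: fermrsm
Title: Modular Response-Surface Modeling of Multivariate Fermentation Responses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analyzing multivariate responses measured on a
    face-centered central composite design, built around a three-stage
    workflow: autoscaling with exploratory numeric summaries, agglomerative
    hierarchical clustering of response variables under a correlation
    distance together with principal component analysis, and per-cluster
    first-principal-component surrogates modeled by forward stepwise
    polynomial regression with partial F-tests. Includes a synthetic-data
    generator that emulates a 31-run, 18-response wine fermentation study
    with known modular ground truth, a design generator and validator for
    face-centered central composite designs, reconstruction of member
    responses from fitted surrogate models, and a configurable end-to-end
    pipeline with a thin command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
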