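Package: devconn
Title: Sign-Aware Developmental Connectomics on Longitudinal Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds signed functional-connectivity graphs from regional time
    series or correlation matrices, computes segregation and integration
    metrics (Onnela weighted clustering, weighted local efficiency,
    participation coefficient) under absolute-value and positive-only edge
    treatments, quantifies per-node age effects with penalized-spline mixed
    models (adjusted R-squared differences between full and age-free null
    models), and tests spatial alignment of those effects with a
    sensorimotor-association cortical axis using hemisphere-symmetric spin
    permutations. Includes a synthetic longitudinal cohort generator with
    planted developmental gradients so the full pipeline is testable without
    access to restricted neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    mgcv,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
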