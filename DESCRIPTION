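Package: connectokit
Title: Individual-Level Functional Connectome Mapping and Edge-Centric
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Personalized large-scale functional network mapping from
    resting-state BOLD time series via spatially regularized non-negative
    matrix factorization, followed by node- and edge-wise functional
    network connectivity, graph-theoretic network attributes with
    small-world indices against degree-preserving nulls, edge-community
    detection, amplitude co-fluctuation (RSS) and transition statistics,
    and an ANCOVA/FDR group-comparison and clinical-correlation layer.
    Includes a synthetic multi-subject cohort generator with planted
    group covariance effects, motion traces and clinical scores, so the
    full pipeline can be exercised and validated without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    signal,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
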