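Package: behavconn
Title: Transdiagnostic Behavioural Profiling and Functional Connectome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline linking data-driven profiles of childhood behavioural
    difficulties to functional brain organisation. Behavioural profiles are
    derived by consensus community detection on a signed subject-by-subject
    correlation network; functional connectomes are proportionally
    thresholded, summarised with weighted graph metrics normalised against
    degree- and weight-preserving random networks, and classified into
    connector and provincial hubs; partial least squares regression with
    repeated cross-validation, permutation tests, and Procrustes-aligned
    bootstrap loadings relates connectivity features to profile membership.
    A synthetic cohort generator with planted behavioural profiles and
    intrinsic-connectivity-network block covariance supports end-to-end
    testing without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    mclust,
    car,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
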