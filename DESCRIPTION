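Package: fearcircuit
Title: Fear-Circuit Structural Features and Trauma-Exposure Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying whether structural summaries of the
    amygdala-centred fear circuit (amygdala, orbitofrontal and ventromedial
    prefrontal cortex, hippocampus, insula, thalamus) can distinguish
    trauma-exposed from trauma-unexposed individuals across recovery stages.
    Provides a longitudinal synthetic-cohort generator with planted group
    effects, extraction of 23 local, region-wise, pair-wise and network
    structural features, covariate adjustment with reference-group
    Z-standardization, point-biserial feature ranking with bootstrap standard
    errors, ridge-penalized logistic regression fitted by iteratively
    reweighted least squares, bootstrap ROC/AUC inference, and a nested
    model search over 4- to 10-feature subsets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
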