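Package: saltscreen
Title: Composite Salt-Tolerance Evaluation and Transcriptomic Screening
    for Crop Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Evaluates salt tolerance of crop genotype panels from
    control/treatment trait measurements: derived physiological traits
    (relative water content, root-shoot ratio, ion-selective transport
    coefficients), per-trait salt tolerance indices, and a membership
    function / PCA-weighted comprehensive salt tolerance index (CSTI)
    with hierarchical three-class grading. Also implements a four-rule
    genotype-contrast screen for salt-tolerance-related differentially
    expressed genes, a lightweight co-expression stage (soft-power
    adjacency, module detection, eigengenes, module-group correlation,
    hub genes), qRT-PCR relative-expression math (2^-ddCt) with RNA-seq
    concordance, and synthetic-data generators with planted ground
    truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
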