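Package: metord
Title: Preprocessing and Principal Coordinate Analysis for LC-MS/MS Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exploratory analysis of untargeted metabolomics feature tables:
    blank-intensity feature filtering, total-ion-current and probabilistic
    quotient normalization, auto and Pareto scaling, a registry of twenty
    dissimilarity measures, classical Principal Coordinate Analysis (PCoA)
    via Gower double-centering, PCA, ordination-file export, and a
    self-contained interactive 3-D scatter export. Includes a synthetic
    feature-table generator with tagged blanks, contaminant features and
    group-structured biological features for end-to-end testing, and a
    command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape,
    cluster,
    optparse
Config/testthat/edition: 3
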