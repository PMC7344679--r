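Package: sensomet
Title: Linking Untargeted LC-MS Metabolite Features to Wine Sensory
    Attributes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline that associates untargeted UPLC-MS molecular
    features with expert sensory attributes of wine. Provides feature-table
    filtering and normalization, NIPALS principal component analysis tolerant
    of missing values, sparse partial least squares regression and
    discriminant analysis with repeated cross-validated hyperparameter
    selection, variable-importance-in-projection (VIP) biomarker scoring,
    bipartite attribute-feature association networks, and putative metabolite
    annotation by exact-mass adduct matching at ppm tolerance with MSI
    confidence levels. A synthetic-data generator with known ground truth
    emulates the two-season, three-cluster-type study design so every stage
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
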