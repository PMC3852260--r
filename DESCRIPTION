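Package: dcspatial
Title: Spatial Analysis of Dendritic Cell Organization in Lymph-Node Cell Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Density-based clustering of dendritic cells (DCs) in lymph-node
    cell-coordinate maps, per-node morphometry (DC fraction, maturity,
    clustered fraction, cluster counts and sizes), DC-T cell co-localization
    within a fixed influence radius, grid-search calibration of the clustering
    parameters against reference annotations, cohort comparison with
    nonparametric tests, and median-split Kaplan-Meier survival
    stratification. Includes a planted-cluster synthetic-node generator with
    ground truth for recovery and calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
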