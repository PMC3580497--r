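Package: algscreen
Title: Phenotypic Screening Analysis for Algal Growth, Motility and
    Photosynthesis Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput small-molecule
    phenotypic screens on microalgae. Scores compound activity from
    plate-reader growth curves as the area under the curve relative to
    in-plate solvent controls, aggregates replicates and calls fitness
    hits at a configurable growth-ratio threshold; classifies acute
    motility/phototaxis and chlorophyll-fluorescence photosynthesis
    phenotypes and cytocidal/cytostatic outcomes; builds Tanimoto
    similarity networks over circular (ECFP-style) substructure
    fingerprints with phenotype attributes for graph visualization
    tools; and trains a Laplacian-corrected naive Bayes model on
    fingerprint features to rank unscreened compound libraries,
    evaluated by enrichment factors under stratified repeated holdout.
    Includes synthetic-data generators (logistic growth plates with
    planted inhibition, SMILES libraries with a planted
    structure-activity relationship) so the full pipeline is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Matrix,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
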