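Package: selectscreen
Title: Ligand-Based Virtual Screening with a Multi-Class Activity
    Classifier and Docking Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A ligand-based virtual-screening pipeline for G
    protein-coupled receptor drug discovery. Curates ChEMBL-style
    bioactivity tables, featurizes compounds as 2048-bit ECFP4 (Morgan
    radius 2) fingerprints via OpenBabel, and trains a seven-class
    feed-forward neural network over pChEMBL activity bins to rank
    screening libraries by predicted activity. Includes a
    receptor-subtype selectivity cross-evaluation protocol with Tanimoto
    dataset diagnostics, percent-rank screening reports, Tanimoto
    similarity search, consensus selection against AutoDock Vina docking
    scores, and a synthetic congeneric-series generator so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
SystemRequirements: OpenBabel (the 'obabel' executable on PATH)
Config/testthat/edition: 3
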