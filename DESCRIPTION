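Package: cwqsar
Title: Monte Carlo Correlation-Weight QSAR with Optimal SMILES Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds one-variable quantitative structure-activity
    relationship (QSAR) models from SMILES strings using optimal
    descriptors of correlation weights (DCW).  Attributes are extracted
    from the SMILES line notation (single tokens, adjacent token pairs,
    and global BOND/NOSP/HALO/PAIR indicators) and from the
    hydrogen-suppressed molecular graph (vertex degrees, first-order
    Morgan extended connectivity, ring codes).  Each attribute receives a
    real-valued correlation weight tuned by a seeded coordinate-wise
    Monte Carlo search that maximizes the correlation between the
    descriptor and the endpoint on a training set; a one-variable linear
    calibration maps the descriptor to the endpoint scale.  The package
    also provides the suite of external-validation criteria used in the
    field (CCC, Q2F1-F3, rm2 metrics, the index of ideality of
    correlation, Golbraikh-Tropsha checks), promoter-stability analysis
    across independent optimization runs, endpoint
    similarity/dissimilarity matrices, and a synthetic-data generator
    with planted weights so every pipeline stage is testable offline.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
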