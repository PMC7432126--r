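Package: paedeg
Title: Entropy-Weighted Composite Biodegradability Scoring and
    Molecular-Field QSAR for Plasticizer Derivatives
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ranking phthalic acid ester (PAE) plasticizers by a
    comprehensive biodegradability index that combines range normalization
    with Shannon-entropy objective weighting of enzyme docking endpoints,
    and for building molecular-field (CoMSIA-style) 3D-QSAR models on the
    composite response: common-skeleton least-squares superposition,
    Gaussian similarity fields (steric, electrostatic, hydrophobic,
    hydrogen-bond donor/acceptor) on a rectangular grid, NIPALS partial
    least squares with leave-one-out cross-validation, external validation,
    response-scrambling stability analysis, and per-field contribution
    accounting.  Also provides substituent-enumeration bookkeeping for
    derivative design, rule-based environmental-friendliness screening of
    candidate derivatives, degradation-pathway energy-barrier aggregation,
    and a seeded synthetic-data generator exercising every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    ChemmineR,
    bio3d,
    mixOmics
Config/testthat/edition: 3
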