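Package: qapair
Title: Quantum-Informed Atom Pair Descriptors for QSAR/QSPR Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantum-informed atom pair (QAP) descriptors for molecular
    property modeling. Canonical Carhart-style atom pairs (element, heavy-atom
    degree, pi electrons, topological distance) are enumerated from SMILES and
    enriched with per-pair aggregates (means and binned histograms) of eleven
    quantum-chemical properties taken from a reference database. Three
    descriptor layouts are provided (sumQAP, hQAP, spQAP) together with the
    applicability-domain filter, a variance filter, reference fingerprints,
    and a repeated cross-validation benchmark harness with random forests,
    baselines, relative metrics and Mann-Whitney comparisons. A seeded
    synthetic molecule and quantum-database generator makes the whole pipeline
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    ranger,
    pROC,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
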