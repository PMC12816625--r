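Package: scpstates
Title: Single-Cell and Mini-Bulk Proteomics of Neutrophil Functional States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for ultra-low-input proteomics of
    human neutrophils: iBAQ/riBAQ intensity normalization and a molecular-weight
    corrected single-cell variant, histone-based proteomic-ruler copy-number
    estimation with detection-sensitivity statistics, blank-derived cell quality
    control, empirical-Bayes moderated differential abundance with Storey
    q-values, shared-nearest-neighbour graph clustering with logistic-regression
    marker tests, and protein-family signature scoring that assigns neutrophil
    functional states (armed, engaged, vital NETs, exhausted, lytic NETs,
    immunosuppressive and angiogenic, vascular immature). Ships a synthetic-data
    generator that emulates the single-cell, mini-bulk and blank runs of such a
    study so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
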