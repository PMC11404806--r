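Package: epicons
Title: Cross-Species Consensus B-Cell Epitope Comparison for Immunoglobulins
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Propensity-based linear B-cell epitope prediction on homologous
    immunoglobulin sequences, two-level consensus-epitope construction (across
    homologs and across prediction algorithms), a 0-1 conservation index,
    global-alignment identity of predicted epitopes against reference heavy
    chains, shared-amino-acid similarity summaries against experimentally
    confirmed reference epitopes, and the supporting distance/neighbor-joining
    tree and structural-overlap (RMSD, TM-score) metrics. Includes a synthetic
    data generator that emulates families of homologous sequences with planted
    conserved epitopes and noisy multi-algorithm predictions, so the whole
    pipeline is testable without external services.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
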