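Package: noduleWaves
Title: Transcriptome Waves and Symbiotic Cell Differentiation in Root Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking the nodule transcriptome of Medicago
    truncatula to host-cell and bacteroid differentiation. Implements
    invariant-gene median normalization of two-channel microarray spot tables
    anchored on a replicated constitutive control, stage-wise differential
    expression by pairwise Welch t-tests, hierarchical clustering of temporal
    expression profiles with wave-activation scoring, Fisher's exact enrichment
    of secretory-pathway categories, flow-cytometry ploidy quantification with
    the endoreduplication index, efficiency-corrected qPCR quantification
    (Pfaffl method), and a rule-based four-category classifier for symbiotic
    mutants. A synthetic-data generator with full ground truth emulates the
    array, flow-cytometry, bacteroid-length and qPCR inputs for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
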