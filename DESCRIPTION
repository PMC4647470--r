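Package: crossomics
Title: Cross-Species Comparative Transcriptomics and Drug-Target Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing tissue transcriptomes and drug targets
    between a model species and human: Gini-index tissue-specificity
    signatures and enrichment scoring, global rank-invariant set (GRSN)
    normalization for cross-platform expression data, coefficient-of-variation
    expression-variability screening with proportion tests and hypergeometric
    over-representation, detection of gene-disrupting mutations (start-codon
    loss, premature stops, frameshift indels) across genomes, a four-stage
    species-specific long non-coding RNA filter cascade with genome presence
    classification and read-vote detection, and structure-derived
    ligand-contact residue conservation mapping. Includes seeded synthetic
    data generators with planted ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    bio3d,
    limma,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
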