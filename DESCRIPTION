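Package: yapmod
Title: Reconstruction and Comparison of Condition-Specific Transcriptional Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers condition-specific transcriptional modules for yeast AP-1
    (Yap-family) transcription factors by integrating three evidence streams:
    consensus differential-expression calls from three variance-modelling
    strategies, transcription-factor dependence from deletion-mutant
    transcriptomes, and in vivo promoter binding from ChIP-chip probe data
    classified with a two-component mixture of linear regressions fitted by EM.
    Downstream stages compare modules across species through reciprocal-best-hit
    orthology and thresholded homology, discover cis-regulatory motifs with
    three complementary algorithms filtered by hypergeometric enrichment and
    merged into IUPAC consensuses, and detect and classify protein-DNA contacts
    in macromolecular structures. A synthetic-data generator with recorded
    ground truth drives every stage, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
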