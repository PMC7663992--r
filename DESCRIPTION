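Package: kleptorecept
Title: Scavenger Receptor and Thrombospondin-Type-1 Repeat Protein
    Discovery from Annotated Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies predicted proteins into scavenger-receptor (SR) and
    thrombospondin-type-1-repeat (TSR) families from Pfam domain hits and
    transmembrane-topology predictions using domain-arrangement rules, scans
    TSP1 domain segments for glycosaminoglycan- and CD36-binding motifs,
    builds sequence-logo frequency matrices, and nominates candidate
    recognition genes from raw read-count matrices by trimmed-mean-of-M-values
    (TMM) normalization and an all-comparisons log2-fold-change selection
    rule. Ships a synthetic-data generator that plants known architectures,
    motifs and differential expression so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
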