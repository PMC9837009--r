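Package: exovar
Title: In Silico Screening of Single-Nucleotide EXO-Motif Variants of a miRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for screening single-nucleotide variants of an
    exosome-sorting motif (EXO-motif) inside a mature miRNA, with the
    hsa-miR-1246 GGAG motif as the worked example. The workflow enumerates
    all substitutions inside the motif window, scans the variant set against
    an RNA-binding-protein consensus-motif table with IUPAC-aware matching
    and homolog-group collapsing, predicts or ingests secondary structures
    and extracts hairpin features, clusters dot-bracket structures by
    Levenshtein distance with DBSCAN, compares tertiary-structure ensembles
    by Kabsch RMSD with single-linkage clustering of ensemble centroids, and
    applies rule-based selection of variants for wet-lab validation. A
    synthetic-data module emulates the external motif database, homology
    annotation, secondary-structure predictions and 3D model ensembles so
    every stage is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
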