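Package: mitocurate
Title: Annotation Curation and Transcript Evidence for Circular
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for curating single-strand circular mitochondrial
    genome annotations, with an emphasis on free-living flatworms
    (triclads). Scans the sense strand for open reading frames under the
    echinoderm/flatworm mitochondrial genetic code (translation table 9)
    with an extended initiator set (ATG/GTG/TTG), refines start codons
    across a species panel by maximizing conserved upstream homology
    while penalizing overlap with the upstream gene, turns stranded
    RNA-seq coverage into single-strand transcription tests, long
    noncoding RNA region calls and cleavage-site (coverage drop-off)
    detections, compares circular gene orders through a minimal tRNA
    deletion-set distance, catalogues noncoding regions, and discovers
    candidate ORFs (putative atp8) with hydropathy-based transmembrane
    and signal-like N-terminus heuristics. A synthetic-data generator
    plants ground truth (start codons, lncRNA intervals, coverage
    drop-offs, tRNA relocations) so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
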