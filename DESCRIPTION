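Package: totiscan
Title: Annotation of Totivirus-Like dsRNA Genomes and -1 Ribosomal
    Frameshifting Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing totivirus-like double-stranded RNA
    genomes from their plus-strand sequence: plus-strand ORF discovery and
    UTR/intergenic architecture, standard-code translation and average-mass
    protein molecular weights, detection of the three -1 programmed
    ribosomal frameshifting elements (slippery heptamer, spacer, H-type
    pseudoknot), construction of the predicted CP-RdRp fusion product,
    comparison of near-identical genomes with silent versus nonsynonymous
    classification of point substitutions, residue mapping and conserved
    RdRp motif scanning via pairwise alignment, and a constraint-satisfying
    synthetic genome generator so the whole pipeline is testable without
    any sequence download. Annotations are exported as GFF3 and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    utils
Suggests:
    seqinr,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
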