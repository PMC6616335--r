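Package: stwinscan
Title: Discovery and In-Silico Splicing of Spliceosomal Twin Introns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects spliceosomal twin introns (stwintrons) in fungal genomic
    sequence by degenerate IUPAC gapped-motif search under explicit
    intron-definition rules (minimum intron length, donor-to-branchpoint and
    branchpoint-to-acceptor distance windows, nearest splice-site pairing),
    and simulates their excision in silico.  The splicing engine iteratively
    removes U2 introns from a primary transcript, optionally branching on
    alternative 3' splice sites, and returns the full splice graph with
    per-nucleotide coordinate provenance, from which exon skipping and
    discontinuous "second order" introns are identified.  A seeded fixture
    generator plants canonical introns, stwintrons, alternative-acceptor
    variants and dual intervening sequences with machine-readable truth
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
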