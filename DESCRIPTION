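Package: mxescan
Title: Prediction of Mutually Exclusive Spliced Exons from Gene Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Search genomic sequences for candidate exons that could be
    spliced mutually exclusively with the exons of an annotated gene
    structure. Candidates are enumerated from splice-site dinucleotide
    compatibility (GT/GC/GG--AG and AT--AC intron patterns), constrained to
    the reading frame and approximate length of the query exon, translated
    in frame, scored by Gotoh affine-gap global alignment against the query
    with the Blosum62 matrix, normalized by the query self-score,
    thresholded, and resolved for overlaps. Includes terminal-exon handling
    via start/stop codons, optional recursive search, classification of
    clusters (internal mutually exclusive, multiple-promoter-like, multiple
    poly(A)-like, tandem-duplication/trans-splice group patterns), an
    annotation-scale screening mode with agreement statistics, a seeded
    synthetic-gene fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    rtracklayer,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
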