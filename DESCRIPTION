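Package: psykit
Title: Motif Screening, Alignment Similarity and Expression Analysis for
    the PSY Peptide Family
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An offline pipeline around the PSY family of small
    tyrosine-sulfated plant signaling peptides: PROSITE-style motif
    parsing and scanning (including the 13-residue PSY domain motif and
    its relaxed five-residue variant), homolog screening of BLAST hits by
    precursor length, E-value and motif position, Needleman-Wunsch global
    alignment with affine gaps and EMBOSS-needle-compatible percent
    identity/similarity, subtilase (SBT1.1/SBT6.1/SBT3.8) cleavage-motif
    annotation, conserved-residue censuses over homolog collections and
    multiple alignments, comparative-Ct (delta-delta-Ct) qPCR analysis
    with a randomization test, and synthetic prepropeptide and Ct-table
    generators with recorded ground truth so every stage is testable
    without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
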