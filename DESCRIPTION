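Package: pathenz
Title: Knowledge-Based Identification of Pathway Enzymes in Plant Sequence Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens peptide, transcript, or genome sequences for candidate
    enzymes of a metabolic pathway (flavonoid biosynthesis shipped as the
    default knowledge base). Candidates are collected by local similarity to
    curated bait sequences with a dual identity / self-score-ratio filter,
    refined through global multiple alignments and nearest-bait phylogenetic
    classification, and screened for functionally relevant amino acid
    residues and domain conservation to predict enzyme functionality.
    Genome input is handled by translated search, grouping of exon hits
    into loci, and stitching of one isoform per locus restricted to
    canonical GT-AG introns. A synthetic-fixture generator plants bait
    families, diagnostic residues, and multi-exon genes with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
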