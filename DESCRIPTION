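Package: varatree
Title: Variation-Aware Short-Read Alignment with Dynamic Variation Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-and-extend alignment of Illumina-style paired-end reads
    against a reference genome augmented with known variants. Single-nucleotide
    variants are folded into a 4-bit per-site encoding of the reference so that
    matching a read base against a site is a one-step bit test; insertions and
    deletions are kept in a positional side index and attached, per seed, to a
    small trie ("variation tree") built on the fly over the local extension
    windows. Seed extension runs a generalized Landau-Vishkin algorithm over all
    haplotype paths of the tree simultaneously, so that known variation is
    traversed at zero edit cost while novel differences are charged Levenshtein
    costs. Alignments found in variant-haplotype coordinates are restored to
    reference-coordinate CIGAR strings for SAM output. Includes a deterministic
    read simulator with planted variants and per-read truth records, and an
    evaluator for mapping accuracy, unmapped and soft-clipped counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
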