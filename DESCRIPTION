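Package: teasv
Title: Split-Read Detection of Transposable Element Insertions from Noisy Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects transposable-element insertion polymorphisms from
    single-molecule long reads by split-read mapping. Provides a seeded,
    banded affine-gap local aligner with BLAST-style scoring, a targeted
    mode that maps new insertions of a known element, an ab initio mode
    that discovers insertions of any library element from similarity
    breakpoints in individual reads, locus-concordance validation,
    breakpoint clustering into insertion calls, read-set characterisation
    (genomic filtering, identity, coverage), a relative copy-number
    utility, and a nanopore-like long-read simulator with planted-insertion
    ground truth for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
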