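Package: fostag
Title: In-Silico Fosmid Tagging and Pooled Mate-Pair Sequence Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for designing C-terminally tagged genomic fosmid
    clones by two-step liquid-culture recombineering (pre-tag insertion
    at the stop codon, cassette exchange, FRT flip-out) and for
    validating clone libraries by pooled mate-pair sequencing of 96-well
    plates (8 row + 12 column pools). Includes a synthetic plate and
    read simulator with realistic defect models (homology-arm
    substitutions, junction indels, un-flipped selection cassettes, PCR
    duplicates), a seed-and-extend read mapper, tag-anchored pair
    classification, pileup variant calling with a binomial-tail phred
    score, cross-pool variant confirmation, and per-clone verdicts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Rcpp,
    Rsamtools,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
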