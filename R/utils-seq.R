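#' @useDynLib fostag, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement nucleotide strings
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Split a sequence into frame-0 codons
#' @param x a single DNA string; trailing bases beyond the last full codon
#'   are dropped.
#' @return character vector of codons.
#' @export
codons <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

#' Does a sequence contain an in-frame stop codon?
#' @param x a single DNA string read in frame 0.
#' @return logical.
#' @export
has_inframe_stop <- function(x) any(codons(x) %in% STOP_CODONS)

# Deterministic pseudo-random DNA under a local RNG that does not disturb
# the caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random DNA sequence
#' @param n length in bases.
#' @param seed optional integer; when given the draw is deterministic and
#'   leaves the global RNG state untouched.
#' @return a single DNA string.
#' @export
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

# Stop-free coding sequence of n_codons codons (never TAA/TAG/TGA).
sense_codons <- local({
  all3 <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                          c("A","C","G","T"), paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Random stop-free coding sequence
#' @param n_codons number of sense codons.
#' @param seed optional integer for a deterministic draw.
#' @return DNA string of length `3 * n_codons` with no in-frame stop.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  draw <- function() paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' Derive a labelled sub-seed from a master seed
#'
#' Deterministically maps a master seed plus string labels to an integer in
#' `[1, 2^31)`, so independent random streams (per clone, per pool, per
#' purpose) can be derived from one run seed.
#'
#' @param seed master integer seed.
#' @param ... label components (coerced to character).
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  lab <- paste(..., sep = "/")
  h <- 0
  for (v in utf8ToInt(lab)) h <- (h * 131 + v) %% 2147483563
  as.integer((as.numeric(seed) %% 2147483563 * 48271 + h) %% 2147483563) + 1L
}

# 0-based half-open interval helpers -------------------------------------

iv <- function(start, end) {
  stopifnot(end >= start)
  c(start = as.integer(start), end = as.integer(end))
}

iv_len <- function(x) x[[2]] - x[[1]]

iv_overlap <- function(a_lo, a_hi, b_lo, b_hi) {
  pmax(0L, pmin(a_hi, b_hi) - pmax(a_lo, b_lo))
}

# substring on 0-based half-open coordinates
subseq0 <- function(x, lo, hi) substr(x, lo + 1L, hi)

# replace [lo, hi) by `ins`
splice0 <- function(x, lo, hi, ins) {
  paste0(substr(x, 1L, lo), ins, substr(x, hi + 1L, nchar(x)))
}

# round half-up to `digits` decimals (base round() is banker's rounding)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
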