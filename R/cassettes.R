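# Tag-cassette registry.
#
# Cassette sequences here are synthetic stand-ins with the structural
# properties of widely used tagging cassettes (element order, lengths that
# are multiples of 3, a canonical 34-nt FRT core, an sGFP-sized fluorophore
# segment). The validation pipeline tests structure, not sequence identity,
# so no sequence download is required.

#' Canonical 34-nt minimal FRT site
#' @export
FRT_CORE <- "GAAGTTCCTATTCTCTAGAAAGTATAGGAACTTC"

# In-frame FRT unit: one pad base on each side places the core in a reading
# phase whose codons (GGA AGT TCC TAT TCT CTA GAA AGT ATA GGA ACT TCA)
# contain no stop. Read in frame 0 the bare core would contain TAG.
FRT_UNIT_5P <- "G"
FRT_UNIT_3P <- "A"

#' Build a C-terminal tagging cassette
#'
#' Returns the default fluorophore tagging cassette: shared epitope linker
#' (2xTY1), fluorophore (sGFP-sized), V5, protease cleavage sites, biotin
#' ligase recognition peptide (BLRP), an FRT-flanked selection operon, and
#' the shared terminal epitope (3xFLAG). The un-flipped form carries the
#' selection operon between two direct-repeat FRT cores; the flipped form
#' (after Flp excision) retains a single in-frame FRT and is stop-free and
#' a multiple of 3 so the fusion protein reads through into the endogenous
#' stop codon.
#'
#' @param name cassette name.
#' @param seed integer seed for the deterministic synthetic segment
#'   sequences.
#' @param operon_len length of the FRT-flanked selection/counter-selection
#'   operon in bases. The default (1500) exceeds the width of the
#'   concordant insert window so that flipped and un-flipped placements of
#'   a mate pair can never both appear concordant.
#' @return an object of class `tag_cassette` with elements `name`,
#'   `segments` (ordered list of `role`/`seq`), `unflipped_seq`,
#'   `flipped_seq`, and `operon_interval` (0-based half-open interval of
#'   the operon plus second FRT within the un-flipped sequence).
#' @export
tag_cassette <- function(name = "TY1-sGFP-V5-BLRP-FLAG", seed = 771001L,
                         operon_len = 1500L) {
  seg <- function(role, s) list(role = role, seq = s)
  segments <- list(
    ty1  = seg("linker-epitope", random_cds(24, derive_seed(seed, "ty1"))),   # 72 nt
    sgfp = seg("fluorophore",    random_cds(238, derive_seed(seed, "sgfp"))), # 714 nt
    v5   = seg("epitope",        random_cds(14, derive_seed(seed, "v5"))),    # 42 nt
    tev  = seg("protease-site",  random_cds(15, derive_seed(seed, "tev"))),   # 45 nt
    blrp = seg("blrp",           random_cds(15, derive_seed(seed, "blrp"))),  # 45 nt
    frtL = seg("frt",            paste0(FRT_UNIT_5P, FRT_CORE)),              # 35 nt
    operon = seg("selection-marker", random_dna(operon_len, derive_seed(seed, "operon"))),
    frtR = seg("frt",            paste0(FRT_CORE, FRT_UNIT_3P)),              # 35 nt
    flag = seg("linker-epitope", random_cds(22, derive_seed(seed, "flag")))   # 66 nt
  )
  unflipped <- paste0(vapply(segments, `[[`, "", "seq"), collapse = "")
  # Flp recombination between the two direct-repeat cores keeps the prefix
  # through the first core and the suffix after the second core.
  pre <- paste0(segments$ty1$seq, segments$sgfp$seq, segments$v5$seq,
                segments$tev$seq, segments$blrp$seq, FRT_UNIT_5P, FRT_CORE)
  flipped <- paste0(pre, FRT_UNIT_3P, segments$flag$seq)
  # un-flipped-specific interval: the operon proper, exclusive of the FRT
  # cores and pads, which are shared with the flipped form and therefore
  # carry no flip-state information
  op_lo <- nchar(pre)
  op_hi <- op_lo + nchar(segments$operon$seq)
  out <- structure(list(
    name = name,
    segments = segments,
    unflipped_seq = unflipped,
    flipped_seq = flipped,
    operon_interval = iv(op_lo, op_hi)
  ), class = "tag_cassette")
  validate_cassette(out)
  out
}

#' Flipped (post-excision) form of a cassette
#' @param cassette a `tag_cassette`.
#' @return DNA string of the flipped form.
#' @export
cassette_flipped_form <- function(cassette) cassette$flipped_seq

count_frt <- function(x) {
  length(gregexpr(FRT_CORE, x, fixed = TRUE)[[1]][
    gregexpr(FRT_CORE, x, fixed = TRUE)[[1]] > 0])
}

#' Validate cassette structural invariants
#'
#' Checks that the flipped form has length 0 mod 3, contains no in-frame
#' stop codon, and contains exactly one FRT core, and that the un-flipped
#' form contains exactly two direct-repeat FRT cores.
#'
#' @param cassette a `tag_cassette`.
#' @return invisibly `TRUE`; stops on violation.
#' @export
validate_cassette <- function(cassette) {
  f <- cassette$flipped_seq
  if (nchar(f) %% 3L != 0L)
    stop("cassette '", cassette$name, "': flipped form length not a multiple of 3")
  if (has_inframe_stop(f))
    stop("cassette '", cassette$name, "': flipped form contains an in-frame stop codon")
  if (count_frt(f) != 1L)
    stop("cassette '", cassette$name, "': flipped form must contain exactly one FRT core")
  if (count_frt(cassette$unflipped_seq) != 2L)
    stop("cassette '", cassette$name, "': un-flipped form must contain exactly two FRT cores")
  invisible(TRUE)
}

#' Build the universal pre-tagging cassette
#'
#' A bacterial selection marker flanked by the first and last
#' epitope-coding segments of the tagging cassette, so that any tagging
#' cassette can later replace the marker by homologous recombination
#' between the shared flanks (cassette exchange).
#'
#' @param cassette the `tag_cassette` whose terminal segments the pre-tag
#'   must share.
#' @param marker_len length of the selection marker (nourseothricin-type),
#'   in bases.
#' @param seed integer seed for the synthetic marker sequence.
#' @return an object of class `pretag_cassette` with `marker`,
#'   `flank5`, `flank3` and `seq`.
#' @export
pretag_cassette <- function(cassette, marker_len = 600L, seed = 771002L) {
  flank5 <- cassette$segments[[1]]$seq
  flank3 <- cassette$segments[[length(cassette$segments)]]$seq
  marker <- random_dna(marker_len, derive_seed(seed, "nat"))
  structure(list(
    marker = marker, flank5 = flank5, flank3 = flank3,
    seq = paste0(flank5, marker, flank3)
  ), class = "pretag_cassette")
}

#' Default cassette registry
#'
#' @return named list of the shipped `tag_cassette` objects.
#' @export
cassette_registry <- function() {
  list(`TY1-sGFP-V5-BLRP-FLAG` = tag_cassette())
}
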