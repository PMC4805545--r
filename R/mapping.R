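# Mapping and mate-pair classification.
#
# References: one entry per clone (the intended, flipped construct) plus
# two shared cassette references -- the flipped tag ("TAG") and the
# un-flipped tag carrying the FRT-flanked selection operon
# ("TAG_UNFLIPPED"). Single reads inside the cassette are common to every
# clone, so the mapper reports them once against the shared cassette
# reference and pair resolution translates them into clone coordinates via
# the clone's tag interval; the genomic mate of the pair is what identifies
# the clone, exactly as in the pooled mate-pair validation design.

REF_TAG <- 1L
REF_TAGU <- 2L

#' Build the validation reference set
#'
#' @param constructs list of intended `engineered_construct` objects in
#'   state `tagged_flipped` (one per clone).
#' @param cassette the `tag_cassette` used.
#' @param roi_pad flank width of the mutation region of interest around the
#'   tag (default 1000).
#' @return object of class `reference_set`: `names`, `seqs`, `meta`
#'   (data.table: ref, name, kind, clone_id, len, tag_lo, tag_hi,
#'   tag_strand, roi_lo, roi_hi), cassette geometry (`flip_len`,
#'   `unflip_len`, `shift`, `operon`).
#' @export
reference_set <- function(constructs, cassette, roi_pad = 1000L) {
  clone_ids <- vapply(constructs, function(x) x$base$clone_id, "")
  seqs <- c(cassette$flipped_seq, cassette$unflipped_seq,
            vapply(constructs, `[[`, "", "seq"))
  nm <- c("TAG", "TAG_UNFLIPPED", clone_ids)
  lens <- nchar(seqs)
  tag_lo <- c(-1L, -1L, vapply(constructs, function(x) x$tag_interval[[1]], 0L))
  tag_hi <- c(-1L, -1L, vapply(constructs, function(x) x$tag_interval[[2]], 0L))
  meta <- data.table::data.table(
    ref = seq_along(seqs), name = nm,
    kind = c("special", "special", rep("construct", length(constructs))),
    clone_id = c(NA_character_, NA_character_, clone_ids),
    len = lens, tag_lo = tag_lo, tag_hi = tag_hi,
    tag_strand = c(NA_character_, NA_character_,
                   vapply(constructs, `[[`, "", "tag_strand")),
    roi_lo = pmax(0L, tag_lo - as.integer(roi_pad)),
    roi_hi = pmin(lens, tag_hi + as.integer(roi_pad)))
  meta[kind == "special", `:=`(roi_lo = -1L, roi_hi = -1L)]
  structure(list(names = nm, seqs = seqs, meta = meta,
                 flip_len = nchar(cassette$flipped_seq),
                 unflip_len = nchar(cassette$unflipped_seq),
                 shift = nchar(cassette$unflipped_seq) - nchar(cassette$flipped_seq),
                 operon = cassette$operon_interval,
                 roi_pad = as.integer(roi_pad)),
            class = "reference_set")
}

#' Map mate-pair reads against a reference set
#'
#' Seed-and-extend mapping of both mates of every pair (both strands, edit
#' distance with gapped fallback). Hits lying entirely within a clone's tag
#' interval are reported once against the shared cassette reference.
#'
#' @param reads reads `data.table` with `read1`/`read2` columns.
#' @param refs a `reference_set`.
#' @param k seed k-mer length.
#' @param max_edits maximal edit distance per read.
#' @param band maximal indel span / alignment band.
#' @return list with `hits` (`data.table`: hit, pair, mate, ref, pos,
#'   strand, edits, span) and `events` (`data.table`: hit, pos, type, ref,
#'   alt).
#' @export
map_pairs <- function(reads, refs, k = 21L, max_edits = 6L, band = 8L) {
  n <- nrow(reads)
  rv <- c(reads$read1, reads$read2)
  res <- .map_reads_cpp(rv, refs$seqs,
                        refs$meta$tag_lo, refs$meta$tag_hi,
                        refs$meta$kind == "special",
                        k = as.integer(k), max_edits = as.integer(max_edits),
                        band = as.integer(band))
  hits <- data.table::as.data.table(res$hits)
  events <- data.table::as.data.table(res$events)
  hits[, hit := .I]
  hits[, mate := data.table::fifelse(read <= n, 1L, 2L)]
  hits[, pair := data.table::fifelse(read <= n, read, read - n)]
  hits[, read := NULL]
  list(hits = hits, events = events)
}

# translate a special (cassette-space) hit/event position into clone
# construct coordinates. `space_len` is the cassette form length.
translate_pos <- function(q, span, tag_lo, tag_strand, space_len) {
  ifelse(tag_strand == "+", tag_lo + q, tag_lo + (space_len - (q + span)))
}

#' Resolve and classify mate pairs
#'
#' For every pair, enumerates candidate joint placements (both mates on one
#' clone construct; one mate on the shared flipped cassette translated into
#' clone coordinates; or one mate on the un-flipped cassette overlapping
#' the selection operon, evaluated in un-flipped construct coordinates),
#' keeps concordant placements (reverse-forward orientation, implied insert
#' within `insert_window`) and picks the best by total edit distance.
#'
#' Classes: `tag_anchored` (one mate overlaps the tag interval, the other
#' is genomic), `genomic_only`, `unflipped_evidence` (one mate on the
#' un-flipped cassette overlapping the operon, the other genomic,
#' concordant in un-flipped coordinates), `discordant` (mapped but no
#' unique concordant placement, including cross-clone ambiguity), and
#' `unmapped`.
#'
#' @param mp result of [map_pairs()].
#' @param reads the reads `data.table` given to [map_pairs()].
#' @param refs a `reference_set`.
#' @param insert_window concordant insert window (default `c(2200, 3700)`,
#'   the mate-pair mapping parameters; the looser prose window
#'   `c(2000, 4000)` is configurable).
#' @param operon_min_overlap minimal aligned overlap with the selection
#'   operon (exclusive of the shared FRT cores) for un-flipped evidence
#'   (default 20, mirroring the tag-anchoring threshold). Only operon
#'   bases distinguish the two cassette forms; an overlap this long cannot
#'   arise from a forced gapped alignment of a flipped-clone read within
#'   the mapper's edit budget.
#' @return `data.table`, one row per pair: pair, pool_id, clone_id, class,
#'   plus placement columns (`pos1`, `end1`, `strand1`, `pos2`, `end2`,
#'   `strand2` in comparison space, `insert`, `score`, `tag_overlap1/2`,
#'   `hit1`, `hit2`, `special1`, `special2`, `space`).
#' @export
resolve_pairs <- function(mp, reads, refs, insert_window = c(2200L, 3700L),
                          operon_min_overlap = 20L) {
  meta <- refs$meta
  h <- data.table::copy(mp$hits)
  h[, kind := meta$kind[ref]]
  out_cols <- c("pair", "clone_ref", "clone_id", "class", "space",
                "pos1", "end1", "strand1", "pos2", "end2", "strand2",
                "insert", "score", "tag_overlap1", "tag_overlap2",
                "hit1", "hit2", "special1", "special2")
  empty <- data.table::data.table(
    pair = integer(0), clone_ref = integer(0), clone_id = character(0),
    class = character(0), space = character(0),
    pos1 = integer(0), end1 = integer(0), strand1 = integer(0),
    pos2 = integer(0), end2 = integer(0), strand2 = integer(0),
    insert = integer(0), score = integer(0),
    tag_overlap1 = integer(0), tag_overlap2 = integer(0),
    hit1 = integer(0), hit2 = integer(0),
    special1 = logical(0), special2 = logical(0))

  h1 <- h[mate == 1L]
  h2 <- h[mate == 2L]
  co <- merge(h1, h2, by = "pair", suffixes = c("1", "2"),
              allow.cartesian = TRUE)
  res <- empty
  if (nrow(co)) {
    # candidate clone reference per combo
    co[, c_ref := data.table::fcase(
      kind1 == "construct" & kind2 == "construct" & ref1 == ref2, ref1,
      kind1 == "construct" & kind2 == "special", ref1,
      kind1 == "special" & kind2 == "construct", ref2,
      default = NA_integer_)]
    co <- co[!is.na(c_ref)]
  }
  if (nrow(co)) {
    co[, `:=`(tag_lo = meta$tag_lo[c_ref], tag_hi = meta$tag_hi[c_ref],
              tstr = meta$tag_strand[c_ref])]
    co[, sp1 := kind1 == "special"]
    co[, sp2 := kind2 == "special"]
    co[, unfl := (sp1 & ref1 == REF_TAGU) | (sp2 & ref2 == REF_TAGU)]
    # translate special-mate coordinates into clone space
    slen <- function(unfl) ifelse(unfl, refs$unflip_len, refs$flip_len)
    co[, `:=`(cpos1 = pos1, cend1 = pos1 + span1, cstr1 = strand1,
              cpos2 = pos2, cend2 = pos2 + span2, cstr2 = strand2)]
    co[sp1 == TRUE, `:=`(
      cpos1 = as.integer(translate_pos(pos1, span1, tag_lo, tstr, slen(unfl))),
      cstr1 = data.table::fifelse(tstr == "+", strand1, -strand1))]
    co[sp1 == TRUE, cend1 := cpos1 + span1]
    co[sp2 == TRUE, `:=`(
      cpos2 = as.integer(translate_pos(pos2, span2, tag_lo, tstr, slen(unfl))),
      cstr2 = data.table::fifelse(tstr == "+", strand2, -strand2))]
    co[sp2 == TRUE, cend2 := cpos2 + span2]

    # un-flipped candidates: operon overlap on the cassette mate, genomic
    # mate clear of the tag, genomic coordinates shifted past the insertion
    if (any(co$unfl)) {
      op <- refs$operon
      co[unfl & sp1, op_ov := iv_overlap(pos1, pos1 + span1, op[[1]], op[[2]])]
      co[unfl & sp2, op_ov := iv_overlap(pos2, pos2 + span2, op[[1]], op[[2]])]
      co <- co[!unfl | op_ov >= operon_min_overlap]
      if (nrow(co)) {
        # genomic mate must not overlap the tag for un-flipped evidence
        co[, drop := unfl & ((sp1 & !(cend2 <= tag_lo | cpos2 >= tag_hi)) |
                             (sp2 & !(cend1 <= tag_lo | cpos1 >= tag_hi)))]
        co <- co[drop == FALSE][, drop := NULL]
      }
      if (nrow(co)) {
        co[unfl & sp1 & cpos2 >= tag_hi, `:=`(cpos2 = cpos2 + refs$shift,
                                              cend2 = cend2 + refs$shift)]
        co[unfl & sp2 & cpos1 >= tag_hi, `:=`(cpos1 = cpos1 + refs$shift,
                                              cend1 = cend1 + refs$shift)]
      }
    }
    if (nrow(co)) {
      co[, left1 := cpos1 <= cpos2]
      co[, insert := pmax(cend1, cend2) - pmin(cpos1, cpos2)]
      co[, orient_ok := data.table::fifelse(
        left1, cstr1 == -1L & cstr2 == 1L, cstr2 == -1L & cstr1 == 1L)]
      co <- co[orient_ok & insert >= insert_window[1] & insert <= insert_window[2]]
    }
    if (nrow(co)) {
      co[, `:=`(tag_overlap1 = iv_overlap(cpos1, cend1, tag_lo, tag_hi),
                tag_overlap2 = iv_overlap(cpos2, cend2, tag_lo, tag_hi))]
      co[, class := data.table::fifelse(unfl, "unflipped_evidence",
            data.table::fifelse(tag_overlap1 > 0L | tag_overlap2 > 0L,
                                "tag_anchored", "genomic_only"))]
      co[, score := edits1 + edits2]
      # dedupe identical placements keeping the lowest-edit version (a
      # construct hit and a translated cassette hit can describe the same
      # placement; prefer the cleaner, non-special alignment), then keep
      # best-score placements per pair
      co[, nsp := sp1 + sp2]
      data.table::setorder(co, pair, score, unfl, nsp, cpos1)
      co <- unique(co, by = c("pair", "c_ref", "class", "cpos1", "cpos2",
                              "cstr1", "cstr2"))
      co[, best := min(score), by = pair]
      co <- co[score == best]
      co[, n_clone := data.table::uniqueN(c_ref), by = pair]
      ambiguous <- unique(co[n_clone > 1L, pair])
      co <- co[n_clone == 1L]
      # deterministic tie-break within a clone: prefer the flipped-space
      # interpretation over un-flipped evidence at equal edit distance
      co <- co[, .SD[1], by = pair]
      res <- co[, .(pair, clone_ref = c_ref,
                    clone_id = meta$clone_id[c_ref], class,
                    space = data.table::fifelse(unfl, "U", "F"),
                    pos1 = cpos1, end1 = cend1, strand1 = cstr1,
                    pos2 = cpos2, end2 = cend2, strand2 = cstr2,
                    insert, score, tag_overlap1, tag_overlap2,
                    hit1 = hit1, hit2 = hit2,
                    special1 = sp1, special2 = sp2)]
    } else ambiguous <- integer(0)
  } else ambiguous <- integer(0)

  # fill in non-concordant pairs
  all_pairs <- data.table::data.table(pair = seq_len(nrow(reads)))
  res <- merge(all_pairs, res, by = "pair", all.x = TRUE)
  mapped <- unique(h$pair)
  res[is.na(class), class := data.table::fifelse(pair %in% mapped,
                                                 "discordant", "unmapped")]
  if (length(ambiguous)) res[pair %in% ambiguous, class := "discordant"]
  if ("pool_id" %in% names(reads)) res[, pool_id := reads$pool_id[pair]]
  if ("pair_id" %in% names(reads)) res[, pair_id := reads$pair_id[pair]]
  if ("clone_id" %in% names(reads)) res[, true_clone := reads$clone_id[pair]]
  res[]
}

#' Classify a single mate pair
#'
#' Single-pair interface over the pair-resolution logic: takes one
#' alignment hit per mate and returns the pair class and implied insert.
#'
#' @param hit1,hit2 lists (or single-row data.frames) with fields `ref`
#'   (reference index or name in the reference set), `pos` (0-based),
#'   `strand` (+1/-1), `span` (aligned reference length) and optionally
#'   `edits`.
#' @param refs a `reference_set`.
#' @param insert_window concordant insert window.
#' @return list with `class` and `insert` (NA unless concordant).
#' @export
classify_pair <- function(hit1, hit2, refs, insert_window = c(2200L, 3700L)) {
  as_row <- function(hh, mate) {
    r <- if (is.character(hh$ref)) match(hh$ref, refs$names) else as.integer(hh$ref)
    data.table::data.table(hit = mate, pair = 1L, mate = mate, ref = r,
                           pos = as.integer(hh$pos),
                           strand = as.integer(hh$strand),
                           edits = as.integer(if (is.null(hh$edits)) 0L else hh$edits),
                           span = as.integer(hh$span))
  }
  mp <- list(hits = data.table::rbindlist(list(as_row(hit1, 1L), as_row(hit2, 2L))),
             events = data.table::data.table())
  reads <- data.table::data.table(read1 = "", read2 = "")
  res <- resolve_pairs(mp, reads, refs, insert_window = insert_window)
  list(class = res$class[1], insert = res$insert[1])
}

# ---------------------------------------------------------------------------
# SAM export / import (real-data mode)

cigar_from_events <- function(pos, span, ev) {
  # events within one hit, construct a CIGAR over the reference span
  if (is.null(ev) || !nrow(ev)) return(sprintf("%dM", span))
  ev <- ev[order(ev$pos)]
  ops <- character(0)
  cur <- pos
  for (i in seq_len(nrow(ev))) {
    e <- ev[i]
    if (e$type == "X") next           # mismatches stay inside M
    gap <- (if (e$type == "I") e$pos else e$pos) - cur
    if (gap > 0) ops <- c(ops, sprintf("%dM", gap))
    if (e$type == "I") { ops <- c(ops, sprintf("%dI", nchar(e$alt))); cur <- e$pos }
    if (e$type == "D") { ops <- c(ops, sprintf("%dD", nchar(e$ref))); cur <- e$pos + nchar(e$ref) }
  }
  if (pos + span - cur > 0) ops <- c(ops, sprintf("%dM", pos + span - cur))
  paste(ops, collapse = "")
}

#' Export alignment hits as SAM
#'
#' Minimal single-end SAM records (one per hit) against the reference set,
#' suitable for re-ingestion with [ingest_sam()].
#'
#' @param mp result of [map_pairs()].
#' @param reads the reads `data.table` given to [map_pairs()].
#' @param refs a `reference_set`.
#' @param path output SAM path.
#' @return invisibly `path`.
#' @export
export_sam <- function(mp, reads, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(refs$names))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", refs$names[i], nchar(refs$seqs[i])), con)
  h <- mp$hits
  ev <- mp$events
  if (nrow(h)) {
    lines <- vapply(seq_len(nrow(h)), function(i) {
      r <- h[i]
      seqs <- if (r$mate == 1L) reads$read1 else reads$read2
      s <- seqs[r$pair]
      if (r$strand == -1L) s <- revcomp(s)
      flag <- if (r$strand == -1L) 16L else 0L
      cig <- cigar_from_events(r$pos, r$span, ev[hit == r$hit])
      qname <- if ("pair_id" %in% names(reads))
        sprintf("%s/%d", reads$pair_id[r$pair], r$mate)
      else sprintf("pair%d/%d", r$pair, r$mate)
      sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
              qname, flag, refs$names[r$ref], r$pos + 1L, cig, s, r$edits)
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

parse_cigar <- function(cig) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cig)[[1]]
  toks <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Ingest alignments from a SAM file
#'
#' Real-data mode: converts standard alignment records into the internal
#' hit/event tables. Secondary and supplementary records are dropped;
#' mismatch events are reconstructed by comparing the read to the reference
#' through the CIGAR.
#'
#' @param path SAM file path.
#' @param refs a `reference_set` whose names match the SAM references.
#' @return list with `hits` and `events` tables plus `reads` (the read
#'   table reconstructed from qnames of the form `<pair>/<mate>`), as from
#'   [map_pairs()].
#' @export
ingest_sam <- function(path, refs) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(b$pos)
  qn <- b$qname[keep]
  if (!all(grepl("/[12]$", qn)))
    stop("ingest_sam: query names must end in /1 or /2")
  pair_key <- sub("/[12]$", "", qn)
  mate <- as.integer(sub("^.*/", "", qn))
  pairs <- unique(pair_key)
  pair <- match(pair_key, pairs)
  ref <- match(as.character(b$rname[keep]), refs$names)
  if (anyNA(ref)) stop("ingest_sam: unknown reference name")
  pos <- b$pos[keep] - 1L
  strand <- data.table::fifelse(bitwAnd(b$flag[keep], 16L) > 0L, -1L, 1L)
  cig <- b$cigar[keep]
  seqs <- as.character(b$seq[keep])   # stored in reference orientation

  hits <- data.table::data.table(hit = seq_along(pos), pair = pair, mate = mate,
                                 ref = ref, pos = pos, strand = strand,
                                 edits = 0L, span = 0L)
  evs <- vector("list", length(pos))
  for (i in seq_along(pos)) {
    ci <- parse_cigar(cig[i])
    rp <- pos[i]; qp <- 0L
    rs <- refs$seqs[ref[i]]; qs <- seqs[i]
    rows <- list()
    for (j in seq_along(ci$op)) {
      L <- ci$len[j]
      switch(ci$op[j],
        M = , `=` = , X = {
          a <- substring(qs, qp + 1L, qp + L)
          bref <- subseq0(rs, rp, rp + L)
          if (a != bref) {
            av <- strsplit(a, "")[[1]]; bv <- strsplit(bref, "")[[1]]
            mm <- which(av != bv)
            for (q in mm)
              rows[[length(rows) + 1L]] <- data.table::data.table(
                hit = i, pos = rp + q - 1L, type = "X", ref = bv[q], alt = av[q])
          }
          rp <- rp + L; qp <- qp + L
        },
        I = {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            hit = i, pos = rp, type = "I", ref = "",
            alt = substring(qs, qp + 1L, qp + L))
          qp <- qp + L
        },
        D = {
          rows[[length(rows) + 1L]] <- data.table::data.table(
            hit = i, pos = rp, type = "D", ref = subseq0(rs, rp, rp + L), alt = "")
          rp <- rp + L
        },
        S = { qp <- qp + L },
        stop("unsupported CIGAR op: ", ci$op[j]))
    }
    hits$span[i] <- rp - pos[i]
    evs[[i]] <- if (length(rows)) data.table::rbindlist(rows) else NULL
  }
  events <- data.table::rbindlist(evs[!vapply(evs, is.null, TRUE)])
  if (!nrow(events))
    events <- data.table::data.table(hit = integer(0), pos = integer(0),
                                     type = character(0), ref = character(0),
                                     alt = character(0))
  hits[, edits := 0L]
  if (nrow(events)) {
    ecount <- events[, .(n = sum(pmax(1L, nchar(ref) + nchar(alt)) *
                                   data.table::fifelse(type == "X", 1L, 1L))),
                     by = hit]
    # edit count: substitutions 1 each, indels count their length
    ecount <- events[, .(n = sum(data.table::fifelse(type == "X", 1L,
                                  pmax(nchar(ref), nchar(alt))))), by = hit]
    hits[ecount$hit, edits := ecount$n]
  }
  # reconstruct a reads table so the hits can be resolved
  n_pairs <- length(pairs)
  r1 <- rep("", n_pairs); r2 <- rep("", n_pairs)
  for (i in seq_along(pos)) {
    s <- if (strand[i] == -1L) revcomp(seqs[i]) else seqs[i]
    if (mate[i] == 1L) r1[pair[i]] <- s else r2[pair[i]] <- s
  }
  reads <- data.table::data.table(pair_id = pairs, read1 = r1, read2 = r2)
  list(hits = hits, events = events, reads = reads)
}
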