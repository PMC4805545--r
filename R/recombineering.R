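# In-silico two-step tagging of a fosmid clone:
#   1. design 50-bp homology arms around the stop codon,
#   2. insert the universal pre-tagging cassette in front of the stop codon,
#   3. exchange the pre-tag for the tagging cassette (with FRT-flanked
#      selection operon) via the shared epitope flanks,
#   4. Flp flip-out of the operon, leaving one in-frame FRT,
#   5. frame / stop / 3'-UTR verification.
#
# Constructs are tracked as `engineered_construct` objects with an ordered
# edit log whose replay on the base fosmid reproduces the construct.

new_construct <- function(base, gene_id, state, seq, tag_interval, tag_strand,
                          edit_log, cassette = NULL) {
  structure(list(base = base, gene_id = gene_id, state = state, seq = seq,
                 tag_interval = tag_interval, tag_strand = tag_strand,
                 edit_log = edit_log, cassette = cassette),
            class = "engineered_construct")
}

edit_rec <- function(pos, ref, alt) list(pos = as.integer(pos), ref = ref, alt = alt)

#' Replay an edit log on a sequence
#'
#' Each edit replaces `ref` (which must match) at `pos` (0-based, in the
#' coordinates of the sequence at the time the edit is applied) with `alt`.
#'
#' @param seq starting nucleotide string.
#' @param edit_log list of edits as stored in an `engineered_construct`.
#' @return the edited sequence.
#' @export
apply_edits <- function(seq, edit_log) {
  for (e in edit_log) {
    found <- subseq0(seq, e$pos, e$pos + nchar(e$ref))
    if (found != e$ref)
      stop("edit log replay mismatch at position ", e$pos)
    seq <- splice0(seq, e$pos, e$pos + nchar(e$ref), e$alt)
  }
  seq
}

# orient a cassette-space string into genomic space for the gene's strand
orient <- function(s, strand) if (strand == "+") s else revcomp(s)

#' Design homology arms for pre-tag insertion
#'
#' Arms are reported in coding orientation: `upstream` is the `arm_len`
#' bases ending immediately before the stop codon, `downstream` the
#' `arm_len` bases starting at the stop codon.
#'
#' @param site a tag site from [tag_site()] (genomic coordinates).
#' @param fosmid the `fosmid_clone` to engineer (with sequence).
#' @param arm_len arm length in bases (default 50).
#' @return object of class `homology_arms` with `upstream`, `downstream`,
#'   `arm_len`, `strand` and `ip` (insertion point in fosmid-local 0-based
#'   coordinates).
#' @export
design_homology_arms <- function(site, fosmid, arm_len = 50L) {
  ip <- site$insertion_point - fosmid$interval[[1]]
  n <- nchar(fosmid$sequence)
  if (ip < arm_len || ip + arm_len > n)
    stop("tag site too close to clone edge for ", arm_len, "-bp arms")
  left <- subseq0(fosmid$sequence, ip - arm_len, ip)
  right <- subseq0(fosmid$sequence, ip, ip + arm_len)
  if (site$strand == "+") {
    up <- left; dn <- right
  } else {
    up <- revcomp(right); dn <- revcomp(left)
  }
  if (has_inframe_stop(substr(up, nchar(up) %% 3L + 1L, nchar(up))))
    warning("upstream arm contains an in-frame stop codon")
  structure(list(upstream = up, downstream = dn, arm_len = as.integer(arm_len),
                 strand = site$strand, ip = as.integer(ip)),
            class = "homology_arms")
}

#' Corrupt homology arms with synthesis errors
#'
#' Models oligonucleotide synthesis errors: substitutions and short indels
#' restricted to the arm sequences, deterministic under `seed`.
#'
#' @param arms a `homology_arms` object.
#' @param sub_rate per-base substitution probability.
#' @param indel_rate per-base indel probability.
#' @param seed integer seed.
#' @param max_indel maximal indel length (default 2).
#' @return a `homology_arms` object with a `mutations` data.frame attribute
#'   recording arm, position (0-based within the arm), type, ref and alt.
#' @export
corrupt_oligo <- function(arms, sub_rate, indel_rate = 0, seed = 1L, max_indel = 2L) {
  mut <- data.frame(arm = character(0), pos = integer(0), type = character(0),
                    ref = character(0), alt = character(0))
  do_arm <- function(s, which) {
    n <- nchar(s)
    subs <- which(stats::runif(n) < sub_rate) - 1L
    for (p in subs) {
      ref <- subseq0(s, p, p + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      s <- splice0(s, p, p + 1L, alt)
      mut <<- rbind(mut, data.frame(arm = which, pos = p, type = "X", ref = ref, alt = alt))
    }
    if (indel_rate > 0) {
      idl <- which(stats::runif(n) < indel_rate) - 1L
      for (p in rev(idl)) {
        len <- sample.int(max_indel, 1L)
        if (stats::runif(1) < 0.5 && p + len <= nchar(s)) {
          ref <- subseq0(s, p, p + len)
          s <- splice0(s, p, p + len, "")
          mut <<- rbind(mut, data.frame(arm = which, pos = p, type = "D", ref = ref, alt = ""))
        } else {
          ins <- random_dna(len)
          s <- splice0(s, p, p, ins)
          mut <<- rbind(mut, data.frame(arm = which, pos = p, type = "I", ref = "", alt = ins))
        }
      }
    }
    s
  }
  res <- with_local_seed(seed, {
    u <- do_arm(arms$upstream, "upstream")
    d <- do_arm(arms$downstream, "downstream")
    list(u = u, d = d)
  })
  out <- arms
  out$upstream <- res$u
  out$downstream <- res$d
  attr(out, "mutations") <- mut
  out
}

#' Insert the pre-tagging cassette in front of the stop codon
#'
#' Models recombineering step 2: the linear fragment
#' upstream-arm + pre-tag + downstream-arm recombines with the fosmid; the
#' arm sequences (including any synthesis errors within tolerance) replace
#' the genomic homology regions and the pre-tag lands between the last
#' sense codon and the stop codon.
#'
#' @param fosmid the `fosmid_clone`.
#' @param site tag site from [tag_site()].
#' @param pretag a `pretag_cassette`.
#' @param arms `homology_arms` (possibly corrupted).
#' @param max_mismatch maximal tolerated substitutions per arm before the
#'   recombination is deemed failed (default 2); length differences
#'   (indels) always fail.
#' @return an `engineered_construct` in state `pretagged`, or an object of
#'   class `recombineering_failure` describing the step-2 failure.
#' @export
insert_pretag <- function(fosmid, site, pretag, arms, max_mismatch = 2L) {
  ip <- arms$ip
  al <- arms$arm_len
  up_g <- orient(arms$upstream, site$strand)   # genomic-orientation arm strings
  dn_g <- orient(arms$downstream, site$strand)
  if (site$strand == "-") { tmp <- up_g; up_g <- dn_g; dn_g <- tmp }
  # genomic layout: [ip-al, ip) must match the left arm string, [ip, ip+al) the right
  ref_left <- subseq0(fosmid$sequence, ip - al, ip)
  ref_right <- subseq0(fosmid$sequence, ip, ip + al)
  mm <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  mml <- mm(ref_left, up_g); mmr <- mm(ref_right, dn_g)
  if (mml > max_mismatch || mmr > max_mismatch) {
    return(structure(list(step = 2L, gene_id = site$gene_id,
                          reason = "homology arm mismatch",
                          mismatches = c(left = mml, right = mmr)),
                     class = "recombineering_failure"))
  }
  insert_g <- paste0(up_g, orient(pretag$seq, site$strand), dn_g)
  ref_region <- subseq0(fosmid$sequence, ip - al, ip + al)
  seq <- splice0(fosmid$sequence, ip - al, ip + al, insert_g)
  tag_iv <- iv(ip, ip + nchar(pretag$seq))
  new_construct(fosmid, site$gene_id, "pretagged", seq, tag_iv, site$strand,
                list(edit_rec(ip - al, ref_region, insert_g)))
}

#' Exchange the pre-tag for a tagging cassette
#'
#' Models recombineering step 3: homologous recombination between the
#' epitope flanks shared by the pre-tag and all tagging cassettes replaces
#' the selection marker with the full cassette (including the FRT-flanked
#' selection operon). The flanks are retained exactly once.
#'
#' @param construct an `engineered_construct` in state `pretagged`.
#' @param cassette a `tag_cassette`.
#' @return an `engineered_construct` in state `tagged_unflipped`.
#' @export
exchange_tag <- function(construct, cassette) {
  if (construct$state != "pretagged")
    stop("exchange_tag: construct is not pre-tagged (pre-tag flanks consumed)")
  ti <- construct$tag_interval
  found <- subseq0(construct$seq, ti[[1]], ti[[2]])
  f5 <- cassette$segments[[1]]$seq
  f3 <- cassette$segments[[length(cassette$segments)]]$seq
  expected_start <- orient(if (construct$tag_strand == "+") f5 else f3, "+")
  # verify the shared flanks are present in the construct in coding orientation
  coding <- orient(found, construct$tag_strand)
  if (substr(coding, 1L, nchar(f5)) != f5 ||
      substr(coding, nchar(coding) - nchar(f3) + 1L, nchar(coding)) != f3)
    stop("exchange_tag: pre-tag flanks not found in construct")
  ins <- orient(cassette$unflipped_seq, construct$tag_strand)
  seq <- splice0(construct$seq, ti[[1]], ti[[2]], ins)
  new_iv <- iv(ti[[1]], ti[[1]] + nchar(ins))
  new_construct(construct$base, construct$gene_id, "tagged_unflipped", seq,
                new_iv, construct$tag_strand,
                c(construct$edit_log, list(edit_rec(ti[[1]], found, ins))),
                cassette = cassette)
}

#' Flp-mediated flip-out of the selection operon
#'
#' Models recombineering step 4: recombination between the two
#' direct-repeat FRT cores excises the selection operon, leaving a single
#' FRT positioned in frame after the tag coding sequence. The endogenous
#' stop codon and 3'-UTR downstream of the tag are untouched.
#'
#' @param construct an `engineered_construct` in state `tagged_unflipped`.
#' @return an `engineered_construct` in state `tagged_flipped`.
#' @export
flip_out <- function(construct) {
  if (construct$state != "tagged_unflipped")
    stop("flip_out: construct is not in state tagged_unflipped")
  ti <- construct$tag_interval
  region <- subseq0(construct$seq, ti[[1]], ti[[2]])
  coding <- orient(region, construct$tag_strand)
  hits <- gregexpr(FRT_CORE, coding, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) != 2L)
    stop("flip_out: expected exactly 2 FRT cores in direct orientation, found ",
         length(hits))
  core_len <- nchar(FRT_CORE)
  flipped_coding <- paste0(substr(coding, 1L, hits[1] + core_len - 1L),
                           substr(coding, hits[2] + core_len, nchar(coding)))
  ins <- orient(flipped_coding, construct$tag_strand)
  seq <- splice0(construct$seq, ti[[1]], ti[[2]], ins)
  new_iv <- iv(ti[[1]], ti[[1]] + nchar(ins))
  new_construct(construct$base, construct$gene_id, "tagged_flipped", seq,
                new_iv, construct$tag_strand,
                c(construct$edit_log, list(edit_rec(ti[[1]], region, ins))),
                cassette = construct$cassette)
}

#' Verify reading frame and context of a tagged construct
#'
#' Checks that (a) the inserted tag length is a multiple of 3, (b) the
#' insert contains no in-frame stop codon, (c) the endogenous stop codon is
#' present immediately downstream of the tag in coding orientation, and
#' (d) the 3'-UTR side of the construct is identical to the base fosmid.
#'
#' @param construct an `engineered_construct` in state `tagged_flipped`.
#' @return object of class `frame_report`: a list of logical checks plus
#'   overall `pass`.
#' @export
verify_frame <- function(construct) {
  ti <- construct$tag_interval
  insert <- orient(subseq0(construct$seq, ti[[1]], ti[[2]]), construct$tag_strand)
  chk_len <- nchar(insert) %% 3L == 0L
  chk_stop_free <- !has_inframe_stop(insert)
  if (construct$tag_strand == "+") {
    stop_seq <- subseq0(construct$seq, ti[[2]], ti[[2]] + 3L)
    utr_construct <- substr(construct$seq, ti[[2]] + 1L, nchar(construct$seq))
    base_ip <- ti[[1]]  # insertion point in base coordinates
    utr_base <- substr(construct$base$sequence, base_ip + 1L,
                       nchar(construct$base$sequence))
  } else {
    stop_seq <- revcomp(subseq0(construct$seq, ti[[1]] - 3L, ti[[1]]))
    utr_construct <- substr(construct$seq, 1L, ti[[1]])
    utr_base <- substr(construct$base$sequence, 1L, ti[[1]])
  }
  chk_stop <- stop_seq %in% STOP_CODONS
  chk_utr <- identical(utr_construct, utr_base)
  checks <- c(insert_frame = chk_len, insert_stop_free = chk_stop_free,
              endogenous_stop = chk_stop, utr3_intact = chk_utr)
  structure(list(gene_id = construct$gene_id, checks = checks,
                 pass = all(checks)),
            class = "frame_report")
}

#' Full design-and-tag pipeline for one gene on one fosmid
#'
#' Convenience wrapper running [tag_site()], [design_homology_arms()],
#' [insert_pretag()], [exchange_tag()], [flip_out()] and [verify_frame()].
#'
#' @param fosmid the `fosmid_clone`.
#' @param gene the `gene_model`.
#' @param cassette a `tag_cassette` (default registry cassette).
#' @param arm_len homology-arm length (default 50).
#' @param arms optional pre-built (possibly corrupted) `homology_arms`.
#' @return list with `construct` (state `tagged_flipped`), `report`
#'   (the `frame_report`) and `site`; or a `recombineering_failure`.
#' @export
tag_fosmid <- function(fosmid, gene, cassette = tag_cassette(), arm_len = 50L,
                       arms = NULL) {
  if (!gene$frame_ok)
    return(structure(list(step = 0L, gene_id = gene$gene_id,
                          reason = "CDS length not divisible by 3"),
                     class = "recombineering_failure"))
  site <- tag_site(gene)
  if (is.null(arms)) arms <- design_homology_arms(site, fosmid, arm_len)
  pre <- insert_pretag(fosmid, site, pretag_cassette(cassette), arms)
  if (inherits(pre, "recombineering_failure")) return(pre)
  flipped <- flip_out(exchange_tag(pre, cassette))
  list(construct = flipped, report = verify_frame(flipped), site = site)
}

#' Write engineered constructs to FASTA
#' @param constructs list of `engineered_construct`.
#' @param path output FASTA path.
#' @return invisibly `path`.
#' @export
write_constructs_fasta <- function(constructs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(constructs, `[[`, "", "seq"))
  names(seqs) <- vapply(constructs, function(x) x$base$clone_id, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a TSV edit-log report for engineered constructs
#' @param constructs list of `engineered_construct`.
#' @param path output TSV path.
#' @return invisibly, the report data.frame.
#' @export
write_edit_log <- function(constructs, path) {
  rows <- do.call(rbind, lapply(constructs, function(x) {
    do.call(rbind, lapply(seq_along(x$edit_log), function(i) {
      e <- x$edit_log[[i]]
      data.frame(clone_id = x$base$clone_id, gene_id = x$gene_id, step = i,
                 pos = e$pos, ref_len = nchar(e$ref), alt_len = nchar(e$alt))
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
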