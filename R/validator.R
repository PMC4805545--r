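# Pooled-sequencing validation logic: duplicate removal, anchored tag
# coverage, pileup variant calling in the tag +- 1000 bp region, cross-pool
# confirmation, and per-clone verdicts.

#' Default validator configuration
#'
#' @param insert_window concordant insert window (default `c(2200, 3700)`,
#'   the explicit mate-pair mapping parameters; `c(2000, 4000)` matches the
#'   prose insert estimate and is selectable).
#' @param min_anchor minimal aligned overlap of the tag-side mate with the
#'   tag for anchored coverage (default 20).
#' @param min_cov cross-pool confirmation threshold (default 3).
#' @param min_score phred-scaled variant score cutoff (default 20).
#' @param error_rate sequencing-error null for the variant score.
#' @param confirm_mode `"support"` (>= min_cov variant-supporting
#'   deduplicated reads in each pool, the default, stricter reading) or
#'   `"site_depth"` (>= min_cov total site coverage in each pool).
#' @param require_both_pools_unflipped flag un-flipped only with evidence in
#'   both pools (default TRUE; `FALSE` flags on evidence in any single pool, the protocol-literal rule).
#' @param roi_pad ROI flank width (default 1000).
#' @param k,max_edits,band mapper parameters.
#' @return a named list of class `validator_config`.
#' @export
validator_config <- function(insert_window = c(2200L, 3700L), min_anchor = 20L,
                             min_cov = 3L, min_score = 20, error_rate = 0.01,
                             confirm_mode = c("support", "site_depth"),
                             require_both_pools_unflipped = TRUE,
                             roi_pad = 1000L, k = 21L, max_edits = 6L,
                             band = 8L) {
  structure(list(insert_window = as.integer(insert_window),
                 min_anchor = as.integer(min_anchor),
                 min_cov = as.integer(min_cov), min_score = min_score,
                 error_rate = error_rate,
                 confirm_mode = match.arg(confirm_mode),
                 require_both_pools_unflipped = require_both_pools_unflipped,
                 roi_pad = as.integer(roi_pad), k = as.integer(k),
                 max_edits = as.integer(max_edits), band = as.integer(band)),
            class = "validator_config")
}

#' Remove PCR duplicate pairs
#'
#' Among resolved concordant pairs sharing both mates' placement
#' (reference, positions, strands) within the same pool, exactly one
#' survives (the first in pair order). Idempotent.
#'
#' @param resolved resolved-pairs `data.table` from [resolve_pairs()].
#' @return deduplicated `data.table` (non-concordant rows are kept as is).
#' @export
remove_duplicates <- function(resolved) {
  conc <- resolved[class %in% c("tag_anchored", "genomic_only", "unflipped_evidence")]
  rest <- resolved[!class %in% c("tag_anchored", "genomic_only", "unflipped_evidence")]
  keyc <- c(if ("pool_id" %in% names(conc)) "pool_id", "clone_ref", "space",
            "pos1", "strand1", "pos2", "strand2")
  conc <- conc[order(pair)]
  conc <- unique(conc, by = keyc)
  data.table::rbindlist(list(conc, rest), use.names = TRUE, fill = TRUE)[order(pair)]
}

#' Anchored tag coverage
#'
#' A tag-anchored pair contributes iff its tag-side mate overlaps the tag
#' interval by at least `min_anchor` aligned bases. Coverage is reported
#' per base over the clone's ROI (tag +- roi_pad) from both mates of
#' contributing pairs, plus the fraction of tag bases covered at least
#' once.
#'
#' @param resolved deduplicated resolved pairs (any subset of pools) for
#'   one clone.
#' @param refs a `reference_set`.
#' @param clone_id the clone.
#' @param min_anchor minimal tag overlap (default 20).
#' @return list with `roi` (lo, hi), `coverage` (integer vector over
#'   `[roi_lo, roi_hi)`), `tag_fraction`, and `n_pairs` contributing.
#' @export
anchored_coverage <- function(resolved, refs, clone_id, min_anchor = 20L) {
  cid <- clone_id
  m <- refs$meta[which(refs$meta$clone_id == cid & refs$meta$kind == "construct")]
  stopifnot(nrow(m) == 1L)
  sub <- resolved[clone_ref == m$ref & class == "tag_anchored" &
                    pmax(tag_overlap1, tag_overlap2) >= min_anchor]
  cov <- integer(m$roi_hi - m$roi_lo)
  if (nrow(sub)) {
    add <- function(lo, hi) {
      lo <- pmax(lo, m$roi_lo); hi <- pmin(hi, m$roi_hi)
      ok <- hi > lo
      data.table::data.table(lo = lo[ok], hi = hi[ok])
    }
    segs <- data.table::rbindlist(list(add(sub$pos1, sub$end1),
                                       add(sub$pos2, sub$end2)))
    if (nrow(segs)) {
      d <- integer(length(cov) + 1L)
      i0 <- segs$lo - m$roi_lo + 1L
      i1 <- segs$hi - m$roi_lo + 1L
      for (i in seq_len(nrow(segs))) {
        d[i0[i]] <- d[i0[i]] + 1L
        d[i1[i]] <- d[i1[i]] - 1L
      }
      cov <- cumsum(d[-length(d)])
    }
  }
  tag_idx <- (m$tag_lo - m$roi_lo + 1L):(m$tag_hi - m$roi_lo)
  list(roi = c(m$roi_lo, m$roi_hi), coverage = cov,
       tag_fraction = mean(cov[tag_idx] > 0), n_pairs = nrow(sub))
}

# phred-scaled upper binomial tail: -10 log10 P(X >= k | n, e)
phred_binom_tail <- function(k, n, e) {
  p <- stats::pbinom(k - 1L, n, e, lower.tail = FALSE)
  ifelse(p <= 0, 1000, pmin(1000, -10 * log10(p)))
}

# left-align an indel against the reference sequence (VCF-style
# normalization); substitutions pass through.
normalize_variant <- function(pos, type, ref, alt, refseq) {
  if (type == "X") return(list(pos = pos, ref = ref, alt = alt))
  unit <- if (type == "D") ref else alt
  L <- nchar(unit)
  while (pos > 0L) {
    prev <- subseq0(refseq, pos - 1L, pos)
    last <- substr(unit, L, L)
    if (prev != last) break
    unit <- paste0(prev, substr(unit, 1L, L - 1L))
    pos <- pos - 1L
  }
  if (type == "D") list(pos = pos, ref = unit, alt = "")
  else list(pos = pos, ref = "", alt = unit)
}

normalize_calls <- function(dt, refseq) {
  if (!nrow(dt)) return(dt)
  for (i in seq_len(nrow(dt))) {
    nv <- normalize_variant(dt$pos[i], dt$type[i], dt$ref[i], dt$alt[i], refseq)
    dt$pos[i] <- nv$pos; dt$ref[i] <- nv$ref; dt$alt[i] <- nv$alt
  }
  dt
}

# construct-space placements (one row per mate) of concordant flipped-space
# pairs for one clone, with events translated into construct coordinates.
clone_placements <- function(resolved, mp, refs, clone_ref_idx) {
  sub <- resolved[clone_ref == clone_ref_idx & space == "F" &
                    class %in% c("tag_anchored", "genomic_only")]
  if (!nrow(sub))
    return(list(placements = data.table::data.table(
      pos = integer(0), end = integer(0), hit = integer(0), special = logical(0)),
      events = data.table::data.table(pos = integer(0), type = character(0),
                                      ref = character(0), alt = character(0),
                                      hit = integer(0))))
  pl <- data.table::rbindlist(list(
    sub[, .(pos = pos1, end = end1, hit = hit1, special = special1)],
    sub[, .(pos = pos2, end = end2, hit = hit2, special = special2)]))
  ev <- mp$events[hit %in% pl$hit]
  if (nrow(ev)) {
    ev <- merge(ev, pl[, .(hit, special)], by = "hit")
    m <- refs$meta[ref == clone_ref_idx]
    if (any(ev$special)) {
      Lf <- refs$flip_len
      if (m$tag_strand == "+") {
        ev[special == TRUE, pos := m$tag_lo + pos]
      } else {
        ev[special == TRUE & type == "X",
           `:=`(pos = m$tag_lo + (Lf - pos - 1L), ref = revcomp(ref), alt = revcomp(alt))]
        ev[special == TRUE & type == "D",
           `:=`(pos = m$tag_lo + (Lf - pos - nchar(ref)), ref = revcomp(ref))]
        ev[special == TRUE & type == "I",
           `:=`(pos = m$tag_lo + (Lf - pos), alt = revcomp(alt))]
      }
    }
  }
  list(placements = pl, events = ev)
}

#' Call variants in a clone's ROI for one pool
#'
#' Pileup over the deduplicated concordant pairs of one clone in one pool.
#' A substitution or short indel is called when its phred-scaled score --
#' the upper binomial tail probability of observing at least `k`
#' variant-supporting reads among `n` covering reads under the
#' sequencing-error null -- reaches `min_score`.
#'
#' @param resolved deduplicated resolved pairs of ONE pool.
#' @param mp the [map_pairs()] result the pairs came from.
#' @param refs a `reference_set`.
#' @param clone_id clone to call.
#' @param pool_id pool label recorded in the calls.
#' @param error_rate sequencing-error null (default 0.01).
#' @param min_score phred cutoff (default 20).
#' @return `data.table`: clone_id, pool_id, pos, type, ref, alt, support,
#'   coverage, score (left-normalized indels).
#' @export
call_variants <- function(resolved, mp, refs, clone_id, pool_id = NA_character_,
                          error_rate = 0.01, min_score = 20) {
  cid <- clone_id
  m <- refs$meta[which(refs$meta$clone_id == cid & refs$meta$kind == "construct")]
  stopifnot(nrow(m) == 1L)
  cp <- clone_placements(resolved, mp, refs, m$ref)
  ev <- cp$events
  empty <- data.table::data.table(clone_id = character(0), pool_id = character(0),
                                  pos = integer(0), type = character(0),
                                  ref = character(0), alt = character(0),
                                  support = integer(0), coverage = integer(0),
                                  score = numeric(0))
  if (!nrow(ev)) return(empty)
  ev <- ev[pos >= m$roi_lo & pos < m$roi_hi]
  if (!nrow(ev)) return(empty)
  agg <- ev[, .(support = data.table::uniqueN(hit)), by = .(pos, type, ref, alt)]
  pl <- cp$placements
  agg[, coverage := vapply(pos, function(p) sum(pl$pos <= p & pl$end > p), 0L)]
  agg[, support := pmin(support, coverage)]
  agg[, score := phred_binom_tail(support, coverage, error_rate)]
  out <- agg[score >= min_score & support >= 1L]
  if (!nrow(out)) return(empty)
  out <- normalize_calls(out, refs$seqs[m$ref])
  out <- out[, .(support = max(support), coverage = max(coverage),
                 score = max(score)), by = .(pos, type, ref, alt)]
  out[, `:=`(clone_id = cid, pool_id = ..pool_id)]
  data.table::setcolorder(out, c("clone_id", "pool_id", "pos", "type", "ref",
                                 "alt", "support", "coverage", "score"))
  out[]
}

#' Cross-pool confirmation of variant calls
#'
#' A variant is confirmed iff an identical (position, ref, alt) call exists
#' in both the clone's row pool and column pool, each with sufficient
#' reads: `min_cov` variant-supporting reads per pool in `"support"` mode
#' (default), or `min_cov` site coverage per pool in `"site_depth"` mode.
#'
#' @param row_calls,col_calls call tables from [call_variants()] for the
#'   clone's row and column pool.
#' @param min_cov threshold (default 3).
#' @param mode `"support"` or `"site_depth"`.
#' @return `data.table` of confirmed variants with per-pool support.
#' @export
cross_confirm <- function(row_calls, col_calls, min_cov = 3L,
                          mode = c("support", "site_depth")) {
  mode <- match.arg(mode)
  empty <- data.table::data.table(clone_id = character(0), pos = integer(0),
                                  type = character(0), ref = character(0),
                                  alt = character(0),
                                  support_row = integer(0), support_col = integer(0),
                                  coverage_row = integer(0), coverage_col = integer(0))
  if (!nrow(row_calls) || !nrow(col_calls)) return(empty)
  j <- merge(row_calls, col_calls, by = c("clone_id", "pos", "type", "ref", "alt"),
             suffixes = c("_row", "_col"))
  if (!nrow(j)) return(empty)
  ok <- if (mode == "support") j$support_row >= min_cov & j$support_col >= min_cov
        else j$coverage_row >= min_cov & j$coverage_col >= min_cov
  j <- j[ok, .(clone_id, pos, type, ref, alt,
               support_row, support_col, coverage_row, coverage_col)]
  j[]
}

#' Classify a clone from its validation evidence
#'
#' Category precedence: `no_data` (no tag-anchored pairs in either pool) >
#' `unflipped` > `mutated` (>= 1 confirmed variant) > `mutation_free_full`
#' (no variants, every tag base covered by anchored pairs) >
#' `mutation_free_partial`.
#'
#' @param clone_id clone.
#' @param confirmed confirmed-variant table for the clone.
#' @param unflipped_counts named or length-2 vector of deduplicated
#'   un-flipped-evidence pair counts in (row, col) pool.
#' @param tag_fraction fraction of tag bases covered >= 1 by anchored pairs
#'   over the union of the clone's two pools.
#' @param anchored_counts length-2 vector of tag-anchored pair counts in
#'   (row, col) pool.
#' @param require_both_pools_unflipped see [validator_config()].
#' @return a one-row `data.table` verdict.
#' @export
classify_clone <- function(clone_id, confirmed, unflipped_counts, tag_fraction,
                           anchored_counts, require_both_pools_unflipped = TRUE) {
  unflipped_flag <- if (require_both_pools_unflipped)
    all(unflipped_counts >= 1L) else any(unflipped_counts >= 1L)
  category <-
    if (sum(anchored_counts) == 0L && sum(unflipped_counts) == 0L) "no_data"
    else if (unflipped_flag) "unflipped"
    else if (nrow(confirmed) > 0L) "mutated"
    else if (isTRUE(tag_fraction >= 1)) "mutation_free_full"
    else "mutation_free_partial"
  data.table::data.table(
    clone_id = clone_id, category = category,
    n_confirmed = nrow(confirmed),
    tag_fraction = tag_fraction,
    anchored_row = anchored_counts[1], anchored_col = anchored_counts[2],
    unflipped_row = unflipped_counts[1], unflipped_col = unflipped_counts[2],
    variants = if (nrow(confirmed))
      paste(sprintf("%d%s>%s", confirmed$pos,
                    ifelse(confirmed$ref == "", "-", confirmed$ref),
                    ifelse(confirmed$alt == "", "-", confirmed$alt)),
            collapse = ",") else "")
}

#' Summarize a clone library
#'
#' Per-category counts and percentages (half-up, 1 decimal). Accepts either
#' a verdict table or a named vector of counts with an explicit total (for
#' worked examples from printed counts).
#'
#' @param verdicts verdict `data.table` from [classify_clone()], or a named
#'   numeric vector of category counts.
#' @param total denominator; defaults to the number of verdict rows (the
#'   observed/growing set) or `sum(verdicts)` for a counts vector.
#' @return object of class `library_summary` with `counts`, `total` and
#'   `percent`.
#' @export
summarize_library <- function(verdicts, total = NULL) {
  if (is.numeric(verdicts)) {
    counts <- verdicts
    if (is.null(total)) total <- sum(counts)
  } else {
    if (!nrow(verdicts)) stop("summarize_library: empty input")
    counts <- table(verdicts$category)
    counts <- stats::setNames(as.integer(counts), names(counts))
    if (is.null(total)) total <- nrow(verdicts)
  }
  if (total <= 0) stop("summarize_library: nonpositive total")
  pct <- round_half_up(100 * counts / total, 1)
  structure(list(counts = counts, total = total, percent = pct),
            class = "library_summary")
}

#' @export
print.library_summary <- function(x, ...) {
  cat(sprintf("Library summary (n = %d):\n", x$total))
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %6d  (%.1f%%)\n", nm, x$counts[[nm]], x$percent[[nm]]))
  invisible(x)
}

#' Stratify variant positions relative to the tag
#'
#' Assigns each variant to the homology-arm, junction (+-10 bp of the
#' arm/cassette boundaries) or cassette-internal stratum, or `genomic`
#' outside the arms; used for the mutation-spectrum report.
#'
#' @param calls a call/confirmed table with `clone_id` and `pos`.
#' @param refs a `reference_set`.
#' @param arm_len homology-arm length (default 50).
#' @param junction_halfwidth junction zone half width (default 10).
#' @return the input with a `stratum` column added.
#' @export
mutation_spectrum <- function(calls, refs, arm_len = 50L, junction_halfwidth = 10L) {
  if (!nrow(calls)) { calls$stratum <- character(0); return(calls) }
  meta <- refs$meta
  calls <- data.table::as.data.table(calls)
  calls[, stratum := {
    m <- meta[clone_id == .BY[[1]] & kind == "construct"]
    s <- defect_strata(m$tag_lo, m$tag_hi, arm_len, junction_halfwidth)
    inside <- function(p, mm) any(p >= mm[, 1] & p < mm[, 2])
    vapply(pos, function(p) {
      if (inside(p, s$junction)) "junction"
      else if (inside(p, s$arm)) "arm"
      else if (inside(p, s$internal)) "internal"
      else "genomic"
    }, "")
  }, by = clone_id]
  calls[]
}

#' Run the full pooled validation pipeline
#'
#' Maps all pool reads against the reference set, resolves and classifies
#' pairs, removes PCR duplicates per pool, computes anchored tag coverage,
#' calls variants per pool, cross-confirms between each clone's row and
#' column pool, and emits per-clone verdicts and a library summary.
#'
#' @param reads reads `data.table` with `pool_id`, `pair_id`, `read1`,
#'   `read2` (as from [simulate_plate()] or [read_pool_fastq()]).
#' @param refs a `reference_set`.
#' @param pools a `pool_set` (defines each clone's row and column pool).
#' @param config a [validator_config()].
#' @return object of class `validation_result`: list with `verdicts`,
#'   `summary`, `confirmed`, `calls`, `resolved` (deduplicated),
#'   `coverage` (per clone), and `log` (all parameter values and
#'   divergence flags).
#' @export
validate_pools <- function(reads, refs, pools, config = validator_config()) {
  mp <- map_pairs(reads, refs, k = config$k, max_edits = config$max_edits,
                  band = config$band)
  resolved <- resolve_pairs(mp, reads, refs,
                            insert_window = config$insert_window)
  res <- validate_from_resolved(resolved, mp, refs, pools, config)
  res$log <- c(res$log, list(n_pairs = nrow(reads)))
  res
}

# Core of the validator, shared by the simulation-mode and real-data entry
# points. Clones flagged as un-flipped are not analysed further for
# mutations: reads of the un-flipped cassette forced onto the flipped
# reference would otherwise yield artifactual calls around the FRT scar.
validate_from_resolved <- function(resolved, mp, refs, pools, config) {
  dedup <- remove_duplicates(resolved)
  cp <- pools$clone_pools
  verdicts <- vector("list", nrow(cp))
  calls_all <- list()
  confirmed_all <- list()
  coverage <- list()
  for (i in seq_len(nrow(cp))) {
    cl <- cp$clone_id[i]
    rp <- cp$row_pool[i]; cpid <- cp$col_pool[i]
    m <- refs$meta[refs$meta$clone_id == cl & refs$meta$kind == "construct"]
    sub_row <- dedup[pool_id == rp & clone_ref == m$ref]
    sub_col <- dedup[pool_id == cpid & clone_ref == m$ref]
    anch <- c(sum(sub_row$class == "tag_anchored" &
                    pmax(sub_row$tag_overlap1, sub_row$tag_overlap2) >= config$min_anchor),
              sum(sub_col$class == "tag_anchored" &
                    pmax(sub_col$tag_overlap1, sub_col$tag_overlap2) >= config$min_anchor))
    unfl <- c(sum(sub_row$class == "unflipped_evidence"),
              sum(sub_col$class == "unflipped_evidence"))
    unflipped_flag <- if (config$require_both_pools_unflipped)
      all(unfl >= 1L) else any(unfl >= 1L)
    cov <- anchored_coverage(
      data.table::rbindlist(list(sub_row, sub_col), use.names = TRUE, fill = TRUE),
      refs, cl, min_anchor = config$min_anchor)
    if (!unflipped_flag) {
      rc <- call_variants(sub_row, mp, refs, cl, pool_id = rp,
                          error_rate = config$error_rate,
                          min_score = config$min_score)
      cc <- call_variants(sub_col, mp, refs, cl, pool_id = cpid,
                          error_rate = config$error_rate,
                          min_score = config$min_score)
      conf <- cross_confirm(rc, cc, min_cov = config$min_cov,
                            mode = config$confirm_mode)
    } else {
      # flagged un-flipped: not analysed further for mutations
      rc <- cc <- call_variants(sub_row[0L], mp, refs, cl, pool_id = rp)
      conf <- cross_confirm(rc, cc)
    }
    verdicts[[i]] <- classify_clone(cl, conf, unfl, cov$tag_fraction, anch,
                                    config$require_both_pools_unflipped)
    calls_all[[i]] <- data.table::rbindlist(list(rc, cc))
    confirmed_all[[i]] <- conf
    coverage[[cl]] <- cov
  }
  verdicts <- data.table::rbindlist(verdicts)
  log <- c(unclass(config),
           list(n_clones = nrow(cp),
                divergence = if (config$require_both_pools_unflipped)
                  "unflipped flag requires evidence in both pools (cross-pool mode; original rule flags on any single read)"
                else "unflipped flag uses single-read sufficiency (protocol-literal mode)"))
  structure(list(verdicts = verdicts, summary = summarize_library(verdicts),
                 confirmed = data.table::rbindlist(confirmed_all),
                 calls = data.table::rbindlist(calls_all),
                 resolved = dedup, coverage = coverage, log = log),
            class = "validation_result")
}
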