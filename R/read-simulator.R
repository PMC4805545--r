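# Synthetic mate-pair read simulator.
#
# Emulates the pooled validation libraries: ~3 kb mate-pair fragments
# (reverse-forward orientation), 100 bp reads, per-pool barcodes, with a
# defect model for the observed mutation spectrum (homology-arm
# substitutions from oligo synthesis, junction errors from imprecise
# recombination, un-flipped selection cassettes, PCR duplicates).
#
# Defects are drawn ONCE per clone, before pooling: both the row and the
# column pool sequence aliquots of the same culture, which is what makes
# cross-pool confirmation meaningful. Fragment, error and duplicate draws
# use separate RNG streams so that raising the duplicate rate adds exact
# copies without perturbing the original fragments.

#' Defect specification for the simulator
#'
#' @param arm_substitution_rate per-base substitution rate within the two
#'   homology arms.
#' @param junction_error_rate per-base substitution rate within +-10 bp of
#'   the arm/cassette junctions.
#' @param cassette_internal_rate per-base substitution rate inside the
#'   cassette body.
#' @param unflipped_probability probability that the clone retains the
#'   un-flipped (FRT-operon-FRT) cassette.
#' @param indel_rate per-base indel rate within the junction zones.
#' @param max_indel maximal indel length.
#' @return object of class `defect_spec`.
#' @export
defect_spec <- function(arm_substitution_rate = 0, junction_error_rate = 0,
                        cassette_internal_rate = 0, unflipped_probability = 0,
                        indel_rate = 0, max_indel = 3L) {
  rates <- c(arm_substitution_rate, junction_error_rate,
             cassette_internal_rate, unflipped_probability, indel_rate)
  if (any(rates < 0 | rates > 1)) stop("defect rates must lie in [0, 1]")
  structure(list(arm_substitution_rate = arm_substitution_rate,
                 junction_error_rate = junction_error_rate,
                 cassette_internal_rate = cassette_internal_rate,
                 unflipped_probability = unflipped_probability,
                 indel_rate = indel_rate, max_indel = as.integer(max_indel)),
            class = "defect_spec")
}

# stratum intervals (0-based half-open) around a tag at [lo, hi): the full
# homology arms, the cassette-side junction zones, and the cassette body;
# disjoint so stratum rates compose additively.
defect_strata <- function(lo, hi, arm_len = 50L, junction_halfwidth = 10L) {
  j <- junction_halfwidth
  list(
    junction = rbind(c(lo, lo + j), c(hi - j, hi)),
    arm = rbind(c(lo - arm_len, lo), c(hi, hi + arm_len)),
    internal = rbind(c(lo + j, hi - j))
  )
}

#' Apply the defect model to an engineered clone
#'
#' Draws an un-flipped state and stratified substitutions/indels for one
#' clone, deterministically under `seed`. Mutation positions are recorded
#' in the coordinates of the clone's own (possibly un-flipped) sequence
#' before mutation; for flipped clones these equal the coordinates of the
#' intended reference construct.
#'
#' @param tagged an `engineered_construct` in state `tagged_flipped`.
#' @param spec a [defect_spec()].
#' @param seed integer seed.
#' @param arm_len homology-arm length used in the design (default 50).
#' @return a `clone_instance`: list with `clone_id`, `gene_id`, `seq`
#'   (realized sequence), `tag_lo`/`tag_hi` (tag interval in the realized
#'   sequence, pre-mutation coordinates), `unflipped` (logical) and
#'   `truth` (data.frame pos/type/ref/alt/stratum).
#' @export
apply_defects <- function(tagged, spec, seed, arm_len = 50L) {
  stopifnot(tagged$state == "tagged_flipped")
  with_local_seed(seed, {
    ti <- tagged$tag_interval
    seq <- tagged$seq
    unflipped <- stats::runif(1) < spec$unflipped_probability
    if (unflipped) {
      cas <- tagged$cassette
      seq <- splice0(seq, ti[[1]], ti[[2]], orient(cas$unflipped_seq, tagged$tag_strand))
      tag_hi <- ti[[1]] + nchar(cas$unflipped_seq)
    } else tag_hi <- ti[[2]]
    tag_lo <- ti[[1]]
    strata <- defect_strata(tag_lo, tag_hi, arm_len)
    truth <- data.frame(pos = integer(0), type = character(0), ref = character(0),
                        alt = character(0), stratum = character(0))
    rates <- c(junction = spec$junction_error_rate, arm = spec$arm_substitution_rate,
               internal = spec$cassette_internal_rate)
    claimed <- integer(0)  # junction > arm > internal precedence
    for (st in c("junction", "arm", "internal")) {
      m <- strata[[st]]
      pos <- unlist(lapply(seq_len(nrow(m)), function(i) seq.int(m[i, 1], m[i, 2] - 1L)))
      pos <- setdiff(pos[pos >= 0 & pos < nchar(seq)], claimed)
      claimed <- c(claimed, pos)
      hitp <- pos[stats::runif(length(pos)) < rates[[st]]]
      for (p in hitp) {
        ref <- subseq0(seq, p, p + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        truth <- rbind(truth, data.frame(pos = p, type = "X", ref = ref,
                                         alt = alt, stratum = st))
      }
      if (st == "junction" && spec$indel_rate > 0) {
        idlp <- pos[stats::runif(length(pos)) < spec$indel_rate]
        for (p in idlp) {
          len <- sample.int(spec$max_indel, 1L)
          if (stats::runif(1) < 0.5 && p + len < nchar(seq)) {
            truth <- rbind(truth, data.frame(pos = p, type = "D",
                                             ref = subseq0(seq, p, p + len),
                                             alt = "", stratum = st))
          } else {
            truth <- rbind(truth, data.frame(pos = p, type = "I", ref = "",
                                             alt = random_dna(len), stratum = st))
          }
        }
      }
    }
    seq <- apply_mutations(seq, truth)
    list(clone_id = tagged$base$clone_id, gene_id = tagged$gene_id, seq = seq,
         tag_lo = tag_lo, tag_hi = tag_hi, unflipped = unflipped, truth = truth)
  })
}

# apply a mutation table (pos in original coordinates) to a sequence;
# applied right-to-left so earlier positions stay valid.
apply_mutations <- function(seq, muts) {
  if (!nrow(muts)) return(seq)
  muts <- muts[order(-muts$pos), , drop = FALSE]
  for (i in seq_len(nrow(muts))) {
    m <- muts[i, ]
    seq <- switch(m$type,
      X = splice0(seq, m$pos, m$pos + 1L, m$alt),
      D = splice0(seq, m$pos, m$pos + nchar(m$ref), ""),
      I = splice0(seq, m$pos, m$pos, m$alt),
      stop("unknown mutation type ", m$type))
  }
  seq
}

#' Inject designed mutations into an engineered clone
#'
#' Scenario counterpart of [apply_defects()]: applies an explicit mutation
#' table (or the un-flipped state) instead of random draws.
#'
#' @param tagged an `engineered_construct` in state `tagged_flipped`.
#' @param muts data.frame with columns pos/type/ref/alt/stratum
#'   (reference construct coordinates); may be empty.
#' @param unflipped replace the flipped cassette by the un-flipped form.
#' @return a `clone_instance` (see [apply_defects()]).
#' @export
inject_mutations <- function(tagged, muts = NULL, unflipped = FALSE) {
  ti <- tagged$tag_interval
  seq <- tagged$seq
  tag_hi <- ti[[2]]
  if (unflipped) {
    cas <- tagged$cassette
    seq <- splice0(seq, ti[[1]], ti[[2]], orient(cas$unflipped_seq, tagged$tag_strand))
    tag_hi <- ti[[1]] + nchar(cas$unflipped_seq)
  }
  if (is.null(muts))
    muts <- data.frame(pos = integer(0), type = character(0), ref = character(0),
                       alt = character(0), stratum = character(0))
  if (nrow(muts)) {
    chk <- vapply(seq_len(nrow(muts)), function(i) {
      m <- muts[i, ]
      m$type != "X" || subseq0(seq, m$pos, m$pos + 1L) == m$ref
    }, TRUE)
    if (!all(chk)) stop("inject_mutations: ref allele mismatch")
    seq <- apply_mutations(seq, muts)
  }
  list(clone_id = tagged$base$clone_id, gene_id = tagged$gene_id, seq = seq,
       tag_lo = ti[[1]], tag_hi = tag_hi, unflipped = unflipped, truth = muts)
}

#' Simulate mate-pair reads for one pool
#'
#' Draws ~`insert_mean` fragments over each member clone's region of
#' interest (tag +- 1000 bp) and reports 100 bp reads from both fragment
#' ends in reverse-forward (outward) orientation: read 1 is the reverse
#' complement of the leftmost `read_len` bases, read 2 the rightmost
#' `read_len` bases on the plus strand. `depth` is the target mean
#' read-base coverage over the ROI; the number of pairs per clone is
#' `depth * window / (2 * read_len)` where `window` spans all fragment
#' starts that can touch the ROI.
#'
#' @param pool_id pool identifier.
#' @param members list of `clone_instance` objects in the pool.
#' @param depth target mean fold-coverage over the tag ROI (default 50).
#' @param insert_mean,insert_sd fragment size model (default 3000 +- 1000).
#' @param read_len read length (default 100).
#' @param seq_error_rate per-base sequencing error rate folded into the
#'   reads as substitutions.
#' @param dup_rate probability that a fragment yields one additional exact
#'   PCR duplicate pair.
#' @param seed integer seed; all draws are deterministic given
#'   (seed, pool, clone).
#' @param roi_pad ROI flank width around the tag (default 1000).
#' @return `data.table` with columns pool_id, clone_id (truth), pair_id,
#'   read1, read2, frag_start, insert, dup_of (NA for originals).
#' @export
simulate_pool_reads <- function(pool_id, members, depth = 50,
                                insert_mean = 3000L, insert_sd = 1000L,
                                read_len = 100L, seq_error_rate = 0,
                                dup_rate = 0, seed = 1L, roi_pad = 1000L) {
  stopifnot(depth > 0)
  out <- vector("list", length(members))
  for (mi in seq_along(members)) {
    m <- members[[mi]]
    len <- nchar(m$seq)
    if (len < insert_mean + 2L * insert_sd)
      stop("clone ", m$clone_id, ": construct shorter than insert_mean + 2*insert_sd")
    roi_lo <- max(0L, m$tag_lo - roi_pad)
    roi_hi <- min(len, m$tag_hi + roi_pad)
    w_lo <- max(0L, roi_lo - insert_mean - read_len)
    w_hi <- min(roi_hi, len - 2L * read_len)
    n <- as.integer(ceiling(depth * (w_hi - w_lo) / (2 * read_len)))
    frag <- with_local_seed(derive_seed(seed, pool_id, m$clone_id, "frag"), {
      start <- w_lo + floor(stats::runif(n) * (w_hi - w_lo))
      ins <- as.integer(round(stats::rnorm(n, insert_mean, insert_sd)))
      ins <- pmax(2L * read_len + 50L, pmin(ins, len - start))
      list(start = as.integer(start), ins = ins)
    })
    r1 <- revcomp(substring(m$seq, frag$start + 1L, frag$start + read_len))
    r2 <- substring(m$seq, frag$start + frag$ins - read_len + 1L,
                    frag$start + frag$ins)
    if (seq_error_rate > 0) {
      er <- with_local_seed(derive_seed(seed, pool_id, m$clone_id, "err"), {
        list(r1 = sprinkle_errors(r1, seq_error_rate),
             r2 = sprinkle_errors(r2, seq_error_rate))
      })
      r1 <- er$r1; r2 <- er$r2
    }
    pid <- sprintf("%s:%s:%05d", pool_id, m$clone_id, seq_len(n))
    dt <- data.table::data.table(
      pool_id = pool_id, clone_id = m$clone_id, pair_id = pid,
      read1 = r1, read2 = r2, frag_start = frag$start, insert = frag$ins,
      dup_of = NA_character_)
    if (dup_rate > 0) {
      dup_sel <- with_local_seed(derive_seed(seed, pool_id, m$clone_id, "dup"),
                                 which(stats::runif(n) < dup_rate))
      if (length(dup_sel)) {
        d <- dt[dup_sel]
        d[, dup_of := pair_id]
        d[, pair_id := paste0(pair_id, ":dup")]
        dt <- data.table::rbindlist(list(dt, d))
      }
    }
    out[[mi]] <- dt
  }
  data.table::rbindlist(out)
}

# substitute random wrong bases at rate `rate` per base (vectorized-ish)
sprinkle_errors <- function(reads, rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    s <- reads[i]
    pos <- sample.int(nchar(s), n_err[i])
    for (p in pos) {
      ref <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    }
    reads[i] <- s
  }
  reads
}

#' Simulate all pools of a plate
#'
#' Every occupied well's clone instance contributes reads to exactly its
#' row pool and its column pool.
#'
#' @param pools a `pool_set` from [make_pools()].
#' @param instances named list of `clone_instance` (names = clone ids),
#'   defects already drawn once per clone.
#' @param ... simulation parameters passed to [simulate_pool_reads()].
#' @param seed master seed.
#' @return list with `reads` (one `data.table` over all pools) and
#'   `truth` (list: `defects` per clone, `unflipped` named logical).
#' @export
simulate_plate <- function(pools, instances, ..., seed = 1L) {
  if (!nrow(pools$clone_pools)) {
    warning("empty plate: no reads simulated")
    return(list(reads = data.table::data.table(), truth = list()))
  }
  missing <- setdiff(unlist(pools$membership), names(instances))
  if (length(missing)) stop("no clone instance for: ", paste(missing, collapse = ", "))
  per_pool <- lapply(pools$pools$pool_id, function(pid) {
    mem <- pools$membership[[pid]]
    if (!length(mem)) return(NULL)
    simulate_pool_reads(pid, instances[mem], ..., seed = seed)
  })
  reads <- data.table::rbindlist(per_pool[!vapply(per_pool, is.null, TRUE)])
  truth <- list(
    defects = lapply(instances, `[[`, "truth"),
    unflipped = vapply(instances, `[[`, TRUE, "unflipped")
  )
  list(reads = reads, truth = truth)
}

#' Write per-pool FASTQ files
#'
#' @param reads a reads `data.table` from the simulator.
#' @param dir output directory (created if needed); files are
#'   `<pool>_1.fastq` / `<pool>_2.fastq`.
#' @return invisibly, the vector of files written.
#' @export
write_pool_fastq <- function(reads, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (pid in unique(reads$pool_id)) {
    sub <- reads[reads$pool_id == pid, ]
    for (mate in 1:2) {
      seqs <- Biostrings::DNAStringSet(sub[[paste0("read", mate)]])
      names(seqs) <- paste0(sub$pair_id, "/", mate)
      q <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
      f <- file.path(dir, sprintf("%s_%d.fastq", pid, mate))
      Biostrings::writeXStringSet(seqs, f, format = "fastq", qualities = q)
      files <- c(files, f)
    }
  }
  invisible(files)
}

#' Read simulated pool FASTQ files back into a reads table
#'
#' @param dir directory holding `<pool>_1.fastq` / `<pool>_2.fastq` pairs.
#' @return reads `data.table` (pool_id, pair_id, read1, read2).
#' @export
read_pool_fastq <- function(dir) {
  f1 <- sort(list.files(dir, pattern = "_1\\.fastq$", full.names = TRUE))
  out <- lapply(f1, function(f) {
    pid <- sub("_1\\.fastq$", "", basename(f))
    s1 <- Biostrings::readDNAStringSet(f, format = "fastq")
    s2 <- Biostrings::readDNAStringSet(sub("_1\\.fastq$", "_2.fastq", f),
                                       format = "fastq")
    data.table::data.table(pool_id = pid,
                           pair_id = sub("/1$", "", names(s1)),
                           read1 = as.character(s1), read2 = as.character(s2))
  })
  data.table::rbindlist(out)
}
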