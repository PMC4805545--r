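# Synthetic clone libraries: generator for fosmid loci with embedded genes,
# full tagged plates, and designed defect scenarios with ground truth.
#
# Geometry: each synthetic fosmid is 12 kb with the tag insertion point
# near position 4000, so the mutation ROI (tag +- 1 kb) plus the longest
# plausible mate-pair fragment (mean + 3 sd = 6 kb) fits inside the tagged
# construct. The CDS is built from stop-free sense codons ending in TAA so
# homology arms read in frame are stop-free by construction.

#' Generate one synthetic fosmid locus
#'
#' Builds a random fosmid sequence with one embedded protein-coding gene
#' whose stop codon sits at a fixed insertion point, plus its gene model.
#'
#' @param clone_id identifier (also used for the reference name).
#' @param seed integer seed.
#' @param strand gene strand.
#' @param fosmid_len fosmid length (default 12000).
#' @param cds_len CDS length including the stop codon (default 900; must be
#'   divisible by 3).
#' @param utr3_len 3'-UTR length (default 300).
#' @param insertion_point genomic 0-based position of the stop codon's
#'   coding-orientation start (default 4000).
#' @param n_isoforms number of isoforms; extra isoforms share the same
#'   terminus unless `alt_termini`.
#' @param alt_termini add one isoform with a distinct (internal) C-terminus
#'   so the gene has alternative C-termini.
#' @return list with `fosmid` (a `fosmid_clone`) and `gene` (a
#'   `gene_model`).
#' @export
synth_locus <- function(clone_id, seed, strand = "+", fosmid_len = 12000L,
                        cds_len = 900L, utr3_len = 300L,
                        insertion_point = 4000L, n_isoforms = 1L,
                        alt_termini = FALSE) {
  stopifnot(cds_len %% 3L == 0L, cds_len >= 60L)
  ref <- paste0("ctg_", clone_id)
  seq <- random_dna(fosmid_len, derive_seed(seed, clone_id, "fosmid"))
  coding <- paste0(random_cds(cds_len / 3L - 1L, derive_seed(seed, clone_id, "cds")),
                   "TAA")
  ip <- as.integer(insertion_point)
  if (strand == "+") {
    cds_iv <- c(ip + 3L - cds_len, ip + 3L)          # ends with stop triplet
    seq <- splice0(seq, cds_iv[1], cds_iv[2], coding)
    utr3 <- iv(ip + 3L, ip + 3L + utr3_len)
  } else {
    cds_iv <- c(ip - 3L, ip - 3L + cds_len)          # stop triplet at genomic start
    seq <- splice0(seq, cds_iv[1], cds_iv[2], revcomp(coding))
    utr3 <- iv(ip - 3L - utr3_len, ip - 3L)
  }
  isos <- list(isoform(paste0(clone_id, ".t1"), rbind(cds_iv), strand, utr3 = utr3))
  if (n_isoforms > 1L)
    for (j in 2:n_isoforms)
      isos[[j]] <- isoform(paste0(clone_id, ".t", j), rbind(cds_iv), strand,
                           utr3 = utr3)
  if (alt_termini) {
    # a shorter isoform ending 30 codons upstream (alternative C-terminus);
    # the generator does not place a genomic stop at this internal terminus
    off <- 90L
    alt_iv <- if (strand == "+") c(cds_iv[1], cds_iv[2] - off)
              else c(cds_iv[1] + off, cds_iv[2])
    isos[[length(isos) + 1L]] <-
      isoform(paste0(clone_id, ".talt"), rbind(alt_iv), strand, utr3 = utr3)
  }
  list(fosmid = fosmid_clone(clone_id, c(0L, fosmid_len), seq, ref = ref),
       gene = gene_model(paste0("g_", clone_id), strand, isos, ref = ref))
}

#' Generate a synthetic tagged clone library
#'
#' Builds `n` loci (alternating strands), designs and applies the full
#' tagging pipeline to each, and verifies every construct.
#'
#' @param n number of clones.
#' @param seed master seed.
#' @param cassette a `tag_cassette`.
#' @param alt_termini_every give every k-th gene a second isoform with an
#'   alternative C-terminus (0 = never; default every 5th).
#' @param ... forwarded to [synth_locus()].
#' @return list with `loci`, `constructs` (intended, flipped), `reports`
#'   (frame reports) and `cassette`.
#' @export
synth_library <- function(n, seed = 1L, cassette = tag_cassette(),
                          alt_termini_every = 5L, ...) {
  ids <- sprintf("FC%03d", seq_len(n))
  loci <- lapply(seq_len(n), function(i)
    synth_locus(ids[i], seed = derive_seed(seed, ids[i]),
                strand = if (i %% 2L == 0L) "-" else "+",
                alt_termini = alt_termini_every > 0L &&
                  i %% alt_termini_every == 0L, ...))
  names(loci) <- ids
  tagged <- lapply(loci, function(L) tag_fosmid(L$fosmid, L$gene, cassette))
  bad <- vapply(tagged, inherits, TRUE, "recombineering_failure")
  if (any(bad)) stop("tagging failed for: ", paste(ids[bad], collapse = ", "))
  list(loci = loci,
       constructs = lapply(tagged, `[[`, "construct"),
       reports = lapply(tagged, `[[`, "report"),
       cassette = cassette)
}

#' Build a designed validation scenario on one 96-well plate
#'
#' Creates a plate of synthetic tagged clones and injects a designed defect
#' set: clones with known homology-arm substitutions, clones retaining the
#' un-flipped selection cassette, and a clone with a junction deletion.
#' Defects are drawn once per clone (both pools sequence the same culture).
#'
#' @param n_clones number of clones (<= 96, row-major fill).
#' @param seed master seed (choice of affected clones and all sequences).
#' @param n_arm_sub number of clones given arm substitutions (default 3;
#'   the first gets one substitution per arm, the others one upstream-arm
#'   substitution).
#' @param n_unflipped number of clones left un-flipped (default 2).
#' @param n_junction_del number of clones given a 2-bp junction deletion
#'   (default 1).
#' @param junction_del_len deletion length (default 2).
#' @param cassette a `tag_cassette`.
#' @return object of class `validation_scenario`: `library`, `plate`,
#'   `pools`, `refs`, `instances`, and `truth` (`data.table` per clone:
#'   expected category plus the injected mutation table, reference
#'   coordinates).
#' @export
make_validation_scenario <- function(n_clones = 96L, seed = 1L,
                                     n_arm_sub = 3L, n_unflipped = 2L,
                                     n_junction_del = 1L,
                                     junction_del_len = 2L,
                                     cassette = tag_cassette()) {
  lib <- synth_library(n_clones, seed = seed, cassette = cassette)
  ids <- names(lib$constructs)
  wells <- data.frame(
    row = PLATE_ROWS[((seq_len(n_clones) - 1L) %/% 12L) + 1L],
    col = ((seq_len(n_clones) - 1L) %% 12L) + 1L,
    clone_id = ids)
  plate <- plate_layout(wells)
  pools <- make_pools(plate)
  refs <- reference_set(lib$constructs, cassette)

  n_affected <- n_arm_sub + n_unflipped + n_junction_del
  affected <- with_local_seed(derive_seed(seed, "affected"),
                              sample(ids, n_affected))
  arm_ids <- affected[seq_len(n_arm_sub)]
  unfl_ids <- affected[n_arm_sub + seq_len(n_unflipped)]
  jdel_ids <- affected[n_arm_sub + n_unflipped + seq_len(n_junction_del)]

  cycle_alt <- function(ref) c(A = "C", C = "G", G = "T", T = "A")[[ref]]
  instances <- list()
  truth_rows <- list()
  for (cl in ids) {
    con <- lib$constructs[[cl]]
    ti <- con$tag_interval
    muts <- NULL
    unflipped <- cl %in% unfl_ids
    if (cl %in% arm_ids) {
      p_up <- ti[[1]] - 25L
      positions <- if (cl == arm_ids[1]) c(p_up, ti[[2]] + 25L) else p_up
      muts <- data.table::rbindlist(lapply(positions, function(p) {
        ref <- subseq0(con$seq, p, p + 1L)
        data.table::data.table(pos = p, type = "X", ref = ref,
                               alt = cycle_alt(ref), stratum = "arm")
      }))
    }
    if (cl %in% jdel_ids) {
      p <- ti[[1]] - 1L   # deletion across the arm/cassette junction
      muts <- data.table::data.table(
        pos = p, type = "D", ref = subseq0(con$seq, p, p + junction_del_len),
        alt = "", stratum = "junction")
    }
    inst <- inject_mutations(con, muts = if (is.null(muts)) NULL else as.data.frame(muts),
                             unflipped = unflipped)
    instances[[cl]] <- inst
    expected <- if (unflipped) "unflipped"
                else if (!is.null(muts) && nrow(muts)) "mutated"
                else "mutation_free_full"
    truth_rows[[cl]] <- data.table::data.table(
      clone_id = cl, expected_category = expected,
      n_injected = if (is.null(muts)) 0L else nrow(muts))
  }
  truth <- data.table::rbindlist(truth_rows)
  truth_muts <- data.table::rbindlist(lapply(ids, function(cl) {
    tm <- instances[[cl]]$truth
    if (is.null(tm) || !nrow(tm)) return(NULL)
    data.table::data.table(clone_id = cl, data.table::as.data.table(tm))
  }))
  structure(list(library = lib, plate = plate, pools = pools, refs = refs,
                 instances = instances,
                 truth = list(clones = truth, mutations = truth_muts,
                              unflipped = unfl_ids, arm_sub = arm_ids,
                              junction_del = jdel_ids)),
            class = "validation_scenario")
}

#' Simulate and validate a scenario end to end
#'
#' @param scenario a `validation_scenario`.
#' @param depth mean ROI fold-coverage per pool (default 50).
#' @param seq_error_rate sequencing error rate (default 0).
#' @param dup_rate PCR duplicate rate (default 0).
#' @param seed simulation seed.
#' @param config a [validator_config()].
#' @return list with `reads`, `result` (a `validation_result`) and
#'   `scorecard` (see [score_against_truth()]).
#' @export
run_scenario <- function(scenario, depth = 50, seq_error_rate = 0,
                         dup_rate = 0, seed = 1L,
                         config = validator_config()) {
  sim <- simulate_plate(scenario$pools, scenario$instances, depth = depth,
                        seq_error_rate = seq_error_rate, dup_rate = dup_rate,
                        seed = seed)
  result <- validate_pools(sim$reads, scenario$refs, scenario$pools, config)
  list(reads = sim$reads, result = result,
       scorecard = score_against_truth(result, scenario))
}

#' Score a validation result against scenario truth
#'
#' @param result a `validation_result`.
#' @param scenario the `validation_scenario` it was run on.
#' @return list: `verdict_matches` / `n_clones`, `verdict_accuracy`,
#'   `recall` over injected flipped-clone mutations inside the ROI,
#'   `n_false_confirmed` (confirmed calls not in truth), and the
#'   per-clone comparison table.
#' @export
score_against_truth <- function(result, scenario) {
  cmp <- merge(result$verdicts[, .(clone_id, category)],
               scenario$truth$clones, by = "clone_id")
  cmp[, match := category == expected_category]
  tm <- scenario$truth$mutations
  conf <- result$confirmed
  meta <- scenario$refs$meta
  if (!is.null(tm) && nrow(tm)) {
    flipped_ids <- setdiff(unique(tm$clone_id), scenario$truth$unflipped)
    tm <- tm[clone_id %in% flipped_ids]
    # restrict to ROI and normalize like the caller does
    tm <- tm[, {
      m <- meta[clone_id == .BY[[1]] & kind == "construct"]
      .SD[pos >= m$roi_lo & pos < m$roi_hi]
    }, by = clone_id]
    if (nrow(tm)) {
      tm <- tm[, {
        m <- meta[clone_id == .BY[[1]] & kind == "construct"]
        normalize_calls(data.table::copy(.SD), scenario$refs$seqs[m$ref])
      }, by = clone_id]
    }
  }
  if (is.null(tm)) tm <- data.table::data.table(
    clone_id = character(0), pos = integer(0), type = character(0),
    ref = character(0), alt = character(0))
  key <- function(d) paste(d$clone_id, d$pos, d$ref, d$alt)
  truth_keys <- key(tm)
  conf_keys <- if (nrow(conf)) key(conf) else character(0)
  recovered <- truth_keys %in% conf_keys
  false_conf <- conf_keys[!conf_keys %in% truth_keys]
  list(verdict_matches = sum(cmp$match), n_clones = nrow(cmp),
       verdict_accuracy = mean(cmp$match),
       n_truth_mutations = length(truth_keys),
       n_recovered = sum(recovered),
       recall = if (length(truth_keys)) mean(recovered) else NA_real_,
       n_false_confirmed = length(false_conf),
       comparison = cmp)
}
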