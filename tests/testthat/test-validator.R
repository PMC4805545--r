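# A tiny two-clone pooled run shared by several blocks.
mini_run <- function() {
  fixture("mini_run", function() {
    lib <- fix_minilib()
    refs <- reference_set(lib$constructs, lib$cassette)
    wells <- data.frame(row = c("A", "B"), col = c(1, 2),
                        clone_id = names(lib$constructs)[1:2])
    pools <- make_pools(plate_layout(wells))
    instances <- lapply(lib$constructs[1:2], inject_mutations)
    sim <- simulate_plate(pools, instances, depth = 30, dup_rate = 0.3, seed = 19)
    mp <- map_pairs(sim$reads, refs)
    resolved <- resolve_pairs(mp, sim$reads, refs)
    list(lib = lib, refs = refs, pools = pools, reads = sim$reads,
         mp = mp, resolved = resolved)
  })
}

test_that("duplicate removal keeps one pair per placement and is idempotent", {
  mr <- mini_run()
  ded <- remove_duplicates(mr$resolved)
  expect_identical(remove_duplicates(ded), ded)
  # truth oracle: the survivors among concordant pairs of one pool equal the
  # number of distinct original fragments that resolved concordantly
  conc <- mr$resolved[class %in% c("tag_anchored", "genomic_only")]
  conc[, orig := data.table::fifelse(is.na(mr$reads$dup_of[pair]),
                                     mr$reads$pair_id[pair],
                                     mr$reads$dup_of[pair])]
  truth_n <- conc[, data.table::uniqueN(orig), by = pool_id]
  got_n <- ded[class %in% c("tag_anchored", "genomic_only"),
               .N, by = pool_id]
  expect_equal(got_n[order(pool_id)]$N, truth_n[order(pool_id)]$V1)
  # two identical placements collapse to one
  two <- mr$resolved[class == "tag_anchored"][1:2]
  two[2, `:=`(pos1 = two$pos1[1], pos2 = two$pos2[1], strand1 = two$strand1[1],
              strand2 = two$strand2[1], pool_id = two$pool_id[1],
              clone_ref = two$clone_ref[1], space = two$space[1])]
  expect_equal(nrow(remove_duplicates(two)), 1L)
})

test_that("anchored coverage honours the 20 bp anchoring rule at the boundary", {
  mr <- mini_run()
  refs <- mr$refs
  m <- refs$meta[refs$meta$name == "FC001"]
  mk_pair <- function(tag_overlap) {
    # tag-side mate ends tag_overlap bases into the tag; genomic mate left
    tpos <- m$tag_lo - (100L - tag_overlap)
    data.table::data.table(
      pair = 1L, clone_ref = m$ref, clone_id = "FC001", class = "tag_anchored",
      space = "F", pos1 = tpos, end1 = tpos + 100L, strand1 = 1L,
      pos2 = tpos - 2900L, end2 = tpos - 2800L, strand2 = -1L,
      insert = 3000L, score = 0L,
      tag_overlap1 = tag_overlap, tag_overlap2 = 0L,
      hit1 = 1L, hit2 = 2L, special1 = FALSE, special2 = FALSE,
      pool_id = "P1.RA")
  }
  expect_equal(anchored_coverage(mk_pair(19L), refs, "FC001")$n_pairs, 0L)
  a20 <- anchored_coverage(mk_pair(20L), refs, "FC001")
  expect_equal(a20$n_pairs, 1L)
  # brute-force interval stabbing oracle on simulated tag-anchored pairs
  ded <- remove_duplicates(mr$resolved)
  sub <- ded[clone_id == "FC001" & class == "tag_anchored"][1:50]
  got <- anchored_coverage(sub, refs, "FC001")
  brute <- integer(m$roi_hi - m$roi_lo)
  keep <- pmax(sub$tag_overlap1, sub$tag_overlap2) >= 20L
  for (i in which(keep)) {
    for (iv in list(c(sub$pos1[i], sub$end1[i]), c(sub$pos2[i], sub$end2[i]))) {
      lo <- max(iv[1], m$roi_lo); hi <- min(iv[2], m$roi_hi)
      if (hi > lo) {
        idx <- (lo - m$roi_lo + 1L):(hi - m$roi_lo)
        brute[idx] <- brute[idx] + 1L
      }
    }
  }
  expect_equal(got$coverage, brute)
  expect_equal(got$tag_fraction,
               mean(brute[(m$tag_lo - m$roi_lo + 1L):(m$tag_hi - m$roi_lo)] > 0))
})

test_that("the binomial-tail phred score separates real variants from noise", {
  # 10/10 alternative reads at error rate 0.01: certain call (score >= 20)
  expect_gte(phred_binom_tail(10L, 10L, 0.01), 20)
  # 1/30 at 0.01: P(X>=1) = 1 - 0.99^30 = 0.26 -> score ~5.8, filtered
  expect_lt(phred_binom_tail(1L, 30L, 0.01), 20)
  expect_equal(phred_binom_tail(1L, 30L, 0.01),
               -10 * log10(1 - 0.99^30), tolerance = 1e-10)
  # zero mismatching reads produce no calls
  mr <- mini_run()
  ded <- remove_duplicates(mr$resolved)
  calls <- call_variants(ded[pool_id == "P1.RA"], mr$mp, mr$refs, "FC001",
                         pool_id = "P1.RA")
  expect_equal(nrow(calls), 0L)
})

test_that("cross-pool confirmation requires the same allele with support in both pools", {
  base <- data.table::data.table(clone_id = "c", pool_id = "r", pos = 10L,
                                 type = "X", ref = "A", alt = "G",
                                 support = 3L, coverage = 3L, score = 60)
  colp <- data.table::copy(base)[, pool_id := "c"]
  expect_equal(nrow(cross_confirm(base, colp)), 1L)
  # support 3 in row, 2 in column -> not confirmed
  low <- data.table::copy(colp)[, support := 2L]
  expect_equal(nrow(cross_confirm(base, low)), 0L)
  # same position, different allele -> not confirmed
  other <- data.table::copy(colp)[, alt := "T"]
  expect_equal(nrow(cross_confirm(base, other)), 0L)
  # call in row pool only -> not confirmed
  expect_equal(nrow(cross_confirm(base, base[0])), 0L)
  # site-depth semantics accept support 2 when coverage >= 3
  expect_equal(nrow(cross_confirm(base, low, mode = "site_depth")), 1L)
})

test_that("clone classification follows the category precedence", {
  no_conf <- data.table::data.table()
  conf1 <- data.table::data.table(pos = 1L, ref = "A", alt = "G")
  expect_equal(classify_clone("c", no_conf, c(0L, 0L), 1.0, c(10L, 12L))$category,
               "mutation_free_full")
  expect_equal(classify_clone("c", no_conf, c(0L, 0L), 0.9, c(10L, 12L))$category,
               "mutation_free_partial")
  expect_equal(classify_clone("c", conf1, c(0L, 0L), 1.0, c(10L, 12L))$category,
               "mutated")
  # un-flipped dominates mutated
  expect_equal(classify_clone("c", conf1, c(2L, 3L), 1.0, c(10L, 12L))$category,
               "unflipped")
  # single-pool evidence only flags in paper-literal mode
  expect_equal(classify_clone("c", no_conf, c(2L, 0L), 1.0, c(10L, 12L))$category,
               "mutation_free_full")
  expect_equal(classify_clone("c", no_conf, c(2L, 0L), 1.0, c(10L, 12L),
                              require_both_pools_unflipped = FALSE)$category,
               "unflipped")
  expect_equal(classify_clone("c", no_conf, c(0L, 0L), NaN, c(0L, 0L))$category,
               "no_data")
})

test_that("library percentages reproduce the printed worked examples", {
  expect_equal(unname(summarize_library(c(mutation_free = 9580), total = 10995)$percent),
               87.1)
  expect_equal(unname(summarize_library(c(full_coverage = 8005), total = 10995)$percent),
               72.8)
  expect_error(summarize_library(data.table::data.table()), "empty")
  v <- data.table::data.table(category = c("mutated", "mutation_free_full",
                                           "mutation_free_full"))
  s <- summarize_library(v)
  expect_equal(unname(s$percent[["mutation_free_full"]]), 66.7)
})

test_that("variant normalization left-aligns indels consistently with truth", {
  refseq <- paste0(strrep("G", 10), "ATTTTC", strrep("G", 10))
  # deleting either TT inside the homopolymer run normalizes to the run start
  a <- normalize_calls(data.table::data.table(pos = 13L, type = "D",
                                              ref = "TT", alt = ""), refseq)
  b <- normalize_calls(data.table::data.table(pos = 12L, type = "D",
                                              ref = "TT", alt = ""), refseq)
  expect_equal(a$pos, b$pos)
  expect_equal(a$ref, b$ref)
})
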