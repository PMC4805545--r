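mini_instance <- function(con) inject_mutations(con)

test_that("defect rates are validated and the zero spec is a no-op", {
  expect_error(defect_spec(arm_substitution_rate = 1.2), "\\[0, 1\\]")
  con <- fix_minilib()$constructs[[1]]
  inst <- apply_defects(con, defect_spec(), seed = 5)
  expect_identical(inst$seq, con$seq)
  expect_equal(nrow(inst$truth), 0L)
  expect_false(inst$unflipped)
})

test_that("unflipped_probability 1 swaps in the FRT-flanked operon", {
  con <- fix_minilib()$constructs[[2]]  # minus-strand clone
  inst <- apply_defects(con, defect_spec(unflipped_probability = 1), seed = 5)
  expect_true(inst$unflipped)
  cas <- fix_minilib()$cassette
  expect_true(grepl(revcomp(cas$unflipped_seq), inst$seq, fixed = TRUE))
  expect_equal(inst$tag_hi - inst$tag_lo, nchar(cas$unflipped_seq))
})

test_that("arm substitutions follow the binomial oracle and stay in their stratum", {
  con <- fix_minilib()$constructs[[1]]
  rate <- 0.01
  counts <- vapply(1:1000, function(i) {
    inst <- apply_defects(con, defect_spec(arm_substitution_rate = rate), seed = i)
    nrow(inst$truth)
  }, 0L)
  mu <- rate * 2 * 50          # two 50-bp arms
  n <- 1000 * 2 * 50
  sigma <- sqrt(n * rate * (1 - rate)) / 1000
  expect_lt(abs(mean(counts) - mu), 3 * sigma)
  inst <- apply_defects(con, defect_spec(arm_substitution_rate = 0.3), seed = 77)
  ti <- con$tag_interval
  in_arms <- (inst$truth$pos >= ti[[1]] - 50 & inst$truth$pos < ti[[1]]) |
             (inst$truth$pos >= ti[[2]] & inst$truth$pos < ti[[2]] + 50)
  expect_true(all(in_arms))
  expect_true(all(inst$truth$stratum == "arm"))
})

test_that("pool read simulation is seed-deterministic with the mate-pair geometry", {
  con <- fix_minilib()$constructs[[1]]
  inst <- mini_instance(con)
  a <- simulate_pool_reads("pX", list(inst), depth = 5, seed = 21)
  b <- simulate_pool_reads("pX", list(inst), depth = 5, seed = 21)
  expect_identical(a, b)
  expect_true(all(nchar(a$read1) == 100L, nchar(a$read2) == 100L))
  expect_true(all(is.na(a$dup_of)))
  # reverse-forward orientation: read1 is the reverse complement of the
  # fragment's leftmost 100 bases, read2 its rightmost 100 bases
  i <- 1L
  frag <- subseq0(inst$seq, a$frag_start[i], a$frag_start[i] + a$insert[i])
  expect_identical(a$read1[i], revcomp(substr(frag, 1, 100)))
  expect_identical(a$read2[i], substr(frag, nchar(frag) - 99L, nchar(frag)))

  # insert size oracle: mean over ~10^4 pairs within 3 sigma of 3000
  big <- simulate_pool_reads("pY", list(inst), depth = 340, seed = 4)
  expect_gt(nrow(big), 9000)
  expect_lt(abs(mean(big$insert) - 3000), 3 * 1000 / sqrt(nrow(big)) + 15)

  # constructs shorter than insert_mean + 2 sd are rejected
  short <- inst; short$seq <- substr(inst$seq, 1, 4500); short$tag_lo <- 2000L
  short$tag_hi <- 2100L
  expect_error(simulate_pool_reads("pZ", list(short), depth = 5, seed = 1),
               "shorter than")
})

test_that("duplicates are exact flagged copies drawn from an independent stream", {
  inst <- mini_instance(fix_minilib()$constructs[[1]])
  d0 <- simulate_pool_reads("pD", list(inst), depth = 10, dup_rate = 0, seed = 8)
  d3 <- simulate_pool_reads("pD", list(inst), depth = 10, dup_rate = 0.3, seed = 8)
  d5 <- simulate_pool_reads("pD", list(inst), depth = 10, dup_rate = 0.5, seed = 8)
  expect_identical(d0, d3[is.na(dup_of)])          # originals untouched
  expect_identical(d0, d5[is.na(dup_of)])
  dups <- d3[!is.na(dup_of)]
  expect_gt(nrow(dups), 0)
  j <- match(dups$dup_of, d3$pair_id)
  expect_identical(dups$read1, d3$read1[j])
  expect_identical(dups$read2, d3$read2[j])
})

test_that("plate simulation routes each clone to exactly its two pools", {
  lib <- fix_minilib()
  wells <- data.frame(row = c("A", "C"), col = c(1, 7),
                      clone_id = names(lib$constructs)[1:2])
  pools <- make_pools(plate_layout(wells))
  instances <- lapply(lib$constructs[1:2], mini_instance)
  sim <- simulate_plate(pools, instances, depth = 3, seed = 2)
  got <- unique(sim$reads[, c("pool_id", "clone_id")])
  expect_setequal(paste(got$pool_id, got$clone_id),
                  c("P1.RA FC001", "P1.C1 FC001", "P1.RC FC002", "P1.C7 FC002"))
  expect_warning(
    out <- simulate_plate(make_pools(plate_layout(
      data.frame(row = character(0), col = integer(0), clone_id = character(0)))),
      instances, depth = 3, seed = 2),
    "empty plate")
  expect_equal(nrow(out$reads), 0L)
})

test_that("FASTQ output round-trips byte-identically under a fixed seed", {
  inst <- mini_instance(fix_minilib()$constructs[[1]])
  reads <- simulate_pool_reads("poolQ", list(inst), depth = 2, seed = 3)
  d1 <- file.path(tempdir(), "fq1"); d2 <- file.path(tempdir(), "fq2")
  write_pool_fastq(reads, d1)
  write_pool_fastq(simulate_pool_reads("poolQ", list(inst), depth = 2, seed = 3), d2)
  f1 <- file.path(d1, "poolQ_1.fastq")
  expect_identical(tools::md5sum(f1)[[1]],
                   tools::md5sum(file.path(d2, "poolQ_1.fastq"))[[1]])
  back <- read_pool_fastq(d1)
  expect_identical(back$read1, reads$read1)
  expect_identical(back$read2, reads$read2)
  expect_identical(back$pair_id, reads$pair_id)
})
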