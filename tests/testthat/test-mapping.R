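small_refs <- function() {
  lib <- fix_minilib()
  reference_set(lib$constructs, lib$cassette)
}

test_that("error-free reads map uniquely back to their true coordinates", {
  lib <- fix_minilib()
  refs <- small_refs()
  inst <- inject_mutations(lib$constructs[[1]])
  reads <- simulate_pool_reads("p1", list(inst), depth = 60, seed = 17)
  reads <- reads[1:1000]
  mp <- map_pairs(reads, refs)
  h2 <- mp$hits[mate == 2L]   # forward mate, genomic or tag
  truth_pos <- reads$frag_start + reads$insert - 100L
  # translate special hits into construct coordinates for comparison
  m <- refs$meta[refs$meta$clone_id == "FC001" & refs$meta$kind == "construct"]
  h2[, cpos := pos]
  h2[ref == 1L, cpos := m$tag_lo + pos]
  ok <- h2[, any(cpos == truth_pos[pair] & edits == 0L), by = pair]
  expect_equal(sum(ok$V1), length(unique(h2$pair)))
  expect_equal(length(unique(h2$pair)), 1000L)
})

test_that("gapped alignment recovers reads spanning a short deletion", {
  lib <- fix_minilib()
  refs <- small_refs()
  con <- lib$constructs[[1]]
  ti <- con$tag_interval
  del <- data.frame(pos = ti[[1]] - 1L, type = "D",
                    ref = subseq0(con$seq, ti[[1]] - 1L, ti[[1]] + 1L),
                    alt = "", stratum = "junction")
  inst <- inject_mutations(con, del)
  # a read centred on the junction deletion
  rd <- subseq0(inst$seq, ti[[1]] - 51L, ti[[1]] + 49L)
  mp <- map_pairs(data.table::data.table(read1 = revcomp(rd), read2 = rd), refs)
  h <- mp$hits[mate == 2L & ref == refs$meta$ref[refs$meta$name == "FC001"]]
  expect_equal(nrow(h), 1L)
  expect_equal(h$edits, 2L)
  evs <- mp$events[hit == h$hit]
  expect_true(any(evs$type == "D" & nchar(evs$ref) == 2L))
})

test_that("reads inside the shared cassette are reported once on the tag reference", {
  refs <- small_refs()
  cas <- fix_minilib()$cassette
  rd <- substr(cas$flipped_seq, 301, 400)
  mp <- map_pairs(data.table::data.table(read1 = rd, read2 = revcomp(rd)), refs)
  expect_true(all(mp$hits$ref %in% c(1L, 2L)))   # no per-clone duplication
  expect_true(any(mp$hits$ref == 1L & mp$hits$edits == 0L))
})

test_that("classify_pair follows the insert window and reference semantics", {
  refs <- small_refs()
  m <- refs$meta[refs$meta$name == "FC001"]
  tag_hit <- function(pos) list(ref = "FC001", pos = pos, strand = -1, span = 100)
  gen_hit <- function(pos) list(ref = "FC001", pos = pos, strand = 1, span = 100)
  # tag mate + genome mate, implied insert 3000 -> tag_anchored
  r <- classify_pair(tag_hit(m$tag_lo + 500L), gen_hit(m$tag_lo + 500L + 2900L), refs)
  expect_equal(r$class, "tag_anchored")
  expect_equal(r$insert, 3000L)
  # insert 5000 -> discordant
  expect_equal(classify_pair(tag_hit(m$tag_lo + 500L),
                             gen_hit(m$tag_lo + 500L + 4900L), refs)$class,
               "discordant")
  # both genomic at concordant distance -> genomic_only
  expect_equal(classify_pair(list(ref = "FC001", pos = 6000, strand = -1, span = 100),
                             gen_hit(8900L), refs)$class, "genomic_only")
  # mate on the un-flipped cassette operon + genome mate -> unflipped_evidence
  op <- refs$operon
  q <- op[[1]] + 200L
  # genomic mate upstream of the tag; distances computed in un-flipped space
  gpos <- m$tag_lo + q - 2900L
  r2 <- classify_pair(list(ref = "TAG_UNFLIPPED", pos = q, strand = 1, span = 100),
                      list(ref = "FC001", pos = gpos, strand = -1, span = 100), refs)
  expect_equal(r2$class, "unflipped_evidence")
  expect_equal(r2$insert, 3000L)
  # window is configurable: [2200,3700] accepts a strict subset of [2000,4000]
  narrow <- classify_pair(tag_hit(m$tag_lo + 500L),
                          gen_hit(m$tag_lo + 500L + 3800L), refs)
  wide <- classify_pair(tag_hit(m$tag_lo + 500L),
                        gen_hit(m$tag_lo + 500L + 3800L), refs,
                        insert_window = c(2000L, 4000L))
  expect_equal(narrow$class, "discordant")
  expect_equal(wide$class, "tag_anchored")
})

test_that("SAM export and re-ingestion round-trip the alignments", {
  refs <- small_refs()
  inst <- inject_mutations(fix_minilib()$constructs[[1]])
  reads <- simulate_pool_reads("p1", list(inst), depth = 3,
                               seq_error_rate = 0.01, seed = 23)[1:40]
  mp <- map_pairs(reads, refs)
  sam <- tempfile(fileext = ".sam")
  export_sam(mp, reads, refs, sam)
  ing <- ingest_sam(sam, refs)
  key <- function(h, ids) {
    h <- data.table::as.data.table(h)
    h[, .(id = ids[pair], mate, ref, pos, strand, edits, span)][order(id, mate, ref, pos)]
  }
  expect_equal(key(mp$hits, reads$pair_id), key(ing$hits, ing$reads$pair_id),
               ignore_attr = TRUE)
  # events agree after matching hits up
  expect_equal(nrow(mp$events), nrow(ing$events))
  # header-only file -> empty
  empty_sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", refs$names[1],
                                      nchar(refs$seqs[1]))), empty_sam)
  expect_equal(nrow(ingest_sam(empty_sam, refs)$hits), 0L)
})
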