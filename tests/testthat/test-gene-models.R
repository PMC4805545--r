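test_that("GFF3 parsing converts coordinates and applies the frame filter", {
  # single plus-strand gene, CDS 101..160 (1-based closed)
  p <- write_toy_gff(list(list(id = "gA", strand = "+",
                               isoforms = list(rbind(c(101, 160))))))
  gm <- parse_gff(p)
  expect_length(gm, 1)
  expect_equal(unname(gm[["gA"]]$isoforms[[1]]$cds_segments[1, ]), c(100L, 160L))
  expect_true(gm[["gA"]]$frame_ok)

  # empty file -> empty list
  p0 <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", p0)
  expect_length(parse_gff(p0), 0)

  # CDS length not divisible by 3: reported, not dropped
  p2 <- write_toy_gff(list(list(id = "gB", strand = "+",
                                isoforms = list(rbind(c(101, 161))))))
  gm2 <- parse_gff(p2)
  expect_length(gm2, 1)
  expect_false(gm2[["gB"]]$frame_ok)
  expect_equal(attr(gm2, "warnings")$gene_id, "gB")

  # malformed file -> parse error naming the file
  pbad <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "not a gff line at all"), pbad)
  expect_error(parse_gff(pbad), "malformed GFF3")
})

test_that("minus-strand stop codon sits at the genomically smallest CDS base", {
  # hand-walked toy: minus gene, exons 11..20 and 26..31 (1-based), i.e.
  # 0-based segments (10,20), (25,31); coding runs right-to-left so the
  # stop codon occupies bases 10..12 and stop_codon_pos = 10.
  p <- write_toy_gff(list(list(id = "gM", strand = "-",
                               isoforms = list(rbind(c(11, 20), c(26, 31))))))
  gm <- parse_gff(p)
  iso <- gm[["gM"]]$isoforms[[1]]
  expect_equal(iso$stop_codon_pos, 10L)
  ts <- tag_site(gm[["gM"]])
  expect_equal(ts$insertion_point, 13L)  # genomically after the stop triplet
  expect_equal(unname(ts$stop_interval), c(10L, 13L))
})

test_that("tag_site picks the most common C-terminus and flags ties", {
  mk <- function(stops, strand = "+") {
    isos <- lapply(seq_along(stops), function(i)
      isoform(paste0("t", i), rbind(c(stops[i] - 29L, stops[i] + 1L)), strand))
    gene_model("g", strand, isos)
  }
  # all same stop
  expect_equal(tag_site(mk(c(100L, 100L, 100L)))$stop_pos, 100L)
  # majority wins: A,A,B -> A
  ts <- tag_site(mk(c(100L, 100L, 160L)))
  expect_equal(ts$stop_pos, 100L)
  expect_false(ts$tie)
  # tie -> 3'-most w.r.t. strand, flagged (enumerated both candidates)
  ts2 <- tag_site(mk(c(100L, 160L)))
  expect_equal(ts2$stop_pos, 160L)
  expect_true(ts2$tie)
  ts3 <- tag_site(gene_model("g", "-", list(
    isoform("t1", rbind(c(100L, 130L)), "-"),
    isoform("t2", rbind(c(160L, 190L)), "-"))))
  expect_equal(ts3$stop_pos, 100L)  # 3'-most on minus = genomically smallest
  expect_true(ts3$tie)
})

test_that("fosmid selection enforces 2.5 kb flanks on both sides", {
  g <- gene_model("g", "+", list(isoform("t", rbind(c(10000L, 12000L)), "+")))
  cl_ok <- fosmid_clone("C1", c(5000L, 20000L))
  cl_short <- fosmid_clone("C2", c(8000L, 20000L))
  expect_equal(select_fosmid(g, list(cl_ok))$clone_id, "C1")     # flanks 5000/8000
  expect_null(select_fosmid(g, list(cl_short)))                   # upstream 2000 < 2500
  expect_equal(formals(select_fosmid)$min_flank, 2500L)
  # among qualifying clones: maximize the smaller flank, ties by id
  cl_b <- fosmid_clone("B", c(4000L, 18000L))   # min flank 6000
  cl_a <- fosmid_clone("A", c(6000L, 16000L))   # min flank 4000
  expect_equal(select_fosmid(g, list(cl_a, cl_b, cl_ok))$clone_id, "B")
})

test_that("coverage_stats matches a brute-force containment oracle", {
  set.seed(7)
  genes <- lapply(1:50, function(i) {
    lo <- sample.int(80000L, 1)
    gene_model(paste0("g", i), "+",
               list(isoform("t", rbind(c(lo, lo + 3L * sample(200:600, 1))), "+")))
  })
  clones <- lapply(1:30, function(i) {
    lo <- sample.int(70000L, 1)
    fosmid_clone(paste0("c", i), c(lo, lo + 36000L))
  })
  cs <- coverage_stats(genes, clones)
  # independent brute force over all gene x clone pairs
  brute <- sum(vapply(genes, function(g) {
    sp <- range(g$isoforms[[1]]$cds_segments)
    any(vapply(clones, function(cl)
      sp[1] - cl$interval[[1]] >= 2500 && cl$interval[[2]] - sp[2] >= 2500, TRUE))
  }, TRUE))
  expect_equal(cs$covered, brute)
  expect_equal(cs$fraction, brute / 50)
  expect_error(coverage_stats(list(), clones), "empty")
  # worked fractions
  g3 <- genes[1:3]
  expect_equal(coverage_stats(g3, clones)$percent,
               round(100 * coverage_stats(g3, clones)$covered / 3, 1))
})

test_that("gene-model classifications follow their definitions and ignore isoform order", {
  one <- isoform("t1", rbind(c(100L, 400L)), "+")
  two <- isoform("t2", rbind(c(100L, 200L), c(250L, 451L)), "+")
  g_single <- gene_model("gs", "+", list(one))
  g_multi <- gene_model("gm", "+", list(two))
  g_mixed <- gene_model("gx", "+", list(one, two))
  expect_true(is_single_exon_cds(g_single))
  expect_false(is_single_exon_cds(g_multi))
  expect_false(is_single_exon_cds(g_mixed))   # every isoform must be single-exon

  same_stop <- gene_model("g1", "+", list(
    isoform("a", rbind(c(100L, 400L)), "+"),
    isoform("b", rbind(c(10L, 100L), c(160L, 370L)), "+")))
  # same 3'-most base? no: 400-1 vs 370-1 -> alternative termini
  expect_true(has_alternative_c_termini(same_stop))
  expect_false(has_alternative_c_termini(gene_model("g2", "+", list(
    isoform("a", rbind(c(100L, 400L)), "+"),
    isoform("b", rbind(c(130L, 400L)), "+")))))
  # Mhc-like toy: two terminal-exon variants
  mhc <- gene_model("mhc", "+", list(
    isoform("short", rbind(c(0L, 300L), c(400L, 700L)), "+"),
    isoform("long", rbind(c(0L, 300L), c(800L, 1100L)), "+")))
  expect_true(has_alternative_c_termini(mhc))

  # invariance under isoform reordering
  perm <- gene_model("gx", "+", list(two, one))
  expect_equal(is_single_exon_cds(perm), is_single_exon_cds(g_mixed))
  expect_equal(has_alternative_c_termini(perm), has_alternative_c_termini(g_mixed))
})
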