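test_that("cassette registry satisfies its structural invariants", {
  for (cas in cassette_registry()) {
    f <- cassette_flipped_form(cas)
    expect_equal(nchar(f) %% 3L, 0L)
    expect_false(has_inframe_stop(f))
    expect_length(gregexpr(FRT_CORE, f, fixed = TRUE)[[1]], 1L)
    expect_length(gregexpr(FRT_CORE, cas$unflipped_seq, fixed = TRUE)[[1]], 2L)
    # pre-tag flanks are the cassette's first and last epitope segments
    pt <- pretag_cassette(cas)
    expect_identical(pt$flank5, cas$segments[[1]]$seq)
    expect_identical(pt$flank3, cas$segments[[length(cas$segments)]]$seq)
    # un-flipped form is longer than the insert window is wide, so flipped
    # and un-flipped pair placements can never both be concordant
    expect_gt(nchar(cas$unflipped_seq) - nchar(f), 3700 - 2200)
  }
})

test_that("homology arms abut the stop codon in coding orientation", {
  loc <- toy_locus("+")
  site <- tag_site(loc$gene)
  arms <- design_homology_arms(site, loc$fosmid)
  expect_equal(formals(design_homology_arms)$arm_len, 50L)
  expect_equal(nchar(arms$upstream), 50L)
  ip <- site$insertion_point
  expect_identical(arms$upstream, substr(loc$fosmid$sequence, ip - 49L, ip))
  expect_identical(arms$downstream, substr(loc$fosmid$sequence, ip + 1L, ip + 50L))
  expect_identical(substr(arms$downstream, 1, 3), "TAA")
  expect_false(has_inframe_stop(substr(arms$upstream, 3, 50)))

  # minus strand: hand-computed oracle on genomic plus-strand slices
  locm <- toy_locus("-")
  sm <- tag_site(locm$gene)
  am <- design_homology_arms(sm, locm$fosmid, arm_len = 20L)
  ipm <- sm$insertion_point
  expect_identical(am$upstream, revcomp(substr(locm$fosmid$sequence, ipm + 1L, ipm + 20L)))
  expect_identical(am$downstream, revcomp(substr(locm$fosmid$sequence, ipm - 19L, ipm)))
  expect_identical(substr(am$downstream, 1, 3), "TAA")

  # too close to the clone edge -> error
  short_fos <- fosmid_clone("S", c(0L, 60L), random_dna(60, seed = 1))
  fake_site <- list(gene_id = "g", strand = "+", insertion_point = 10L)
  expect_error(design_homology_arms(fake_site, short_fos), "too close")
})

test_that("pre-tag insertion places the marker before the stop and fails on bad arms", {
  loc <- toy_locus("+")
  site <- tag_site(loc$gene)
  cas <- fix_cassette()
  pt <- pretag_cassette(cas)
  arms <- design_homology_arms(site, loc$fosmid)
  con <- insert_pretag(loc$fosmid, site, pt, arms)
  expect_s3_class(con, "engineered_construct")
  expect_equal(nchar(con$seq), nchar(loc$fosmid$sequence) + nchar(pt$seq))
  # junction context equals arm + cassette concatenation (string oracle)
  ti <- con$tag_interval
  expect_identical(subseq0(con$seq, ti[[1]] - 50L, ti[[2]] + 50L),
                   paste0(arms$upstream, pt$seq, arms$downstream))
  # stop codon immediately downstream of the pre-tag
  expect_identical(subseq0(con$seq, ti[[2]], ti[[2]] + 3L), "TAA")

  # strict matching: 3 substitutions exceed the default tolerance of 2
  bad <- arms
  substr(bad$upstream, 1, 3) <- chartr("ACGT", "GTAC", substr(bad$upstream, 1, 3))
  fail <- insert_pretag(loc$fosmid, site, pt, bad)
  expect_s3_class(fail, "recombineering_failure")
  expect_equal(fail$step, 2L)
  # 1 substitution is tolerated and propagated into the construct
  one <- arms
  p1 <- substr(one$upstream, 5, 5)
  substr(one$upstream, 5, 5) <- setdiff(c("A", "C", "G", "T"), p1)[1]
  con1 <- insert_pretag(loc$fosmid, site, pt, one)
  expect_s3_class(con1, "engineered_construct")
  expect_identical(subseq0(con1$seq, con1$tag_interval[[1]] - 50L, con1$tag_interval[[1]]),
                   one$upstream)
})

test_that("cassette exchange and flip-out produce a verified in-frame fusion", {
  loc <- toy_locus("+")
  site <- tag_site(loc$gene)
  cas <- fix_cassette()
  pre <- insert_pretag(loc$fosmid, site, pretag_cassette(cas),
                       design_homology_arms(site, loc$fosmid))
  unf <- exchange_tag(pre, cas)
  expect_equal(unf$state, "tagged_unflipped")
  expect_false(grepl(pretag_cassette(cas)$marker, unf$seq, fixed = TRUE))
  # string oracle: cassette in context between the arms
  ti <- unf$tag_interval
  expect_identical(subseq0(unf$seq, ti[[1]], ti[[2]]), cas$unflipped_seq)
  # exchanging twice errors (pre-tag consumed)
  expect_error(exchange_tag(unf, cas), "pre-tag")

  fl <- flip_out(unf)
  expect_equal(fl$state, "tagged_flipped")
  expect_length(gregexpr(FRT_CORE, subseq0(fl$seq, fl$tag_interval[[1]],
                                           fl$tag_interval[[2]]), fixed = TRUE)[[1]], 1L)
  expect_error(flip_out(fl), "tagged_unflipped")
  # translation oracle: last exon + tag reads through without internal stop
  insert <- subseq0(fl$seq, fl$tag_interval[[1]], fl$tag_interval[[2]])
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(insert)))
  expect_false(grepl("*", aa, fixed = TRUE))
  expect_identical(subseq0(fl$seq, fl$tag_interval[[2]], fl$tag_interval[[2]] + 3L), "TAA")

  rep <- verify_frame(fl)
  expect_true(rep$pass)

  # forged defects are caught: 1-nt deletion breaks the frame check
  broken <- fl
  broken$seq <- splice0(fl$seq, fl$tag_interval[[1]] + 100L, fl$tag_interval[[1]] + 101L, "")
  broken$tag_interval <- iv(fl$tag_interval[[1]], fl$tag_interval[[2]] - 1L)
  expect_false(verify_frame(broken)$checks[["insert_frame"]])
  # in-frame TGA inside the cassette breaks the stop-free check
  stopped <- fl
  p <- fl$tag_interval[[1]] + 99L  # codon boundary inside the tag
  stopped$seq <- splice0(fl$seq, p, p + 3L, "TGA")
  expect_false(verify_frame(stopped)$checks[["insert_stop_free"]])
})

test_that("deleting the tag interval round-trips to the base fosmid, both strands", {
  lib <- fix_minilib()
  for (con in lib$constructs) {
    restored <- paste0(substr(con$seq, 1, con$tag_interval[[1]]),
                       substr(con$seq, con$tag_interval[[2]] + 1L, nchar(con$seq)))
    expect_identical(restored, con$base$sequence)
    expect_identical(apply_edits(con$base$sequence, con$edit_log), con$seq)
    expect_true(verify_frame(con)$pass)
  }
})

test_that("engineering is strand-covariant under reference mirroring", {
  loc <- toy_locus("-", seed = 123)
  cas <- fix_cassette()
  res_minus <- tag_fosmid(loc$fosmid, loc$gene, cas)
  # mirrored locus: reverse-complement the fosmid and flip the gene
  L <- nchar(loc$fosmid$sequence)
  fos_m <- fosmid_clone("TOYm", c(0L, L), revcomp(loc$fosmid$sequence), ref = "m")
  iso <- loc$gene$isoforms[[1]]
  cds_m <- cbind(L - iso$cds_segments[, 2], L - iso$cds_segments[, 1])
  gene_m <- gene_model("gm", "+", list(isoform("t", cds_m, "+")), ref = "m")
  res_plus <- tag_fosmid(fos_m, gene_m, cas)
  expect_identical(revcomp(res_minus$construct$seq), res_plus$construct$seq)
})

test_that("oligo corruption is seed-deterministic with binomially distributed errors", {
  loc <- toy_locus("+")
  arms <- design_homology_arms(tag_site(loc$gene), loc$fosmid)
  same <- corrupt_oligo(arms, 0, seed = 3)
  expect_identical(same$upstream, arms$upstream)
  expect_identical(same$downstream, arms$downstream)
  expect_equal(nrow(attr(same, "mutations")), 0L)
  expect_identical(corrupt_oligo(arms, 0.05, seed = 3),
                   corrupt_oligo(arms, 0.05, seed = 3))
  # binomial oracle: total substitutions over many draws ~ Bin(n*L, rate)
  rate <- 0.02; n <- 4000L; L <- 100L
  tot <- sum(vapply(seq_len(n), function(i)
    nrow(attr(corrupt_oligo(arms, rate, seed = i), "mutations")), 0L))
  mu <- n * L * rate
  sigma <- sqrt(n * L * rate * (1 - rate))
  expect_lt(abs(tot - mu), 3 * sigma)
  # mutation positions restricted to the arms
  m <- attr(corrupt_oligo(arms, 0.2, seed = 11), "mutations")
  expect_true(all(m$pos >= 0 & m$pos < 50))
})
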