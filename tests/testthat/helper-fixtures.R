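# Shared fixtures, built in code. Heavier objects are memoised per session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

fix_cassette <- function() fixture("cassette", function() tag_cassette())

# a small tagged library: 4 clones, alternating strands, one alt-termini gene
fix_minilib <- function() fixture("minilib", function()
  synth_library(4, seed = 42, alt_termini_every = 3L))

# a toy plus-strand gene + fosmid for string-level oracles
toy_locus <- function(strand = "+", seed = 99) {
  synth_locus("TOY", seed = seed, strand = strand, fosmid_len = 12000L,
              cds_len = 300L, utr3_len = 120L)
}

# write a minimal GFF3 with one or more genes; `genes` is a list of lists
# (id, strand, isoforms = list of matrix of 1-based closed CDS (start,end))
write_toy_gff <- function(genes, path = tempfile(fileext = ".gff3"),
                          seqid = "chr1") {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- range(unlist(lapply(g$isoforms, function(m) m)))
    lines <- c(lines, sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              seqid, span[1], span[2], g$strand, g$id))
    for (j in seq_along(g$isoforms)) {
      tid <- sprintf("%s.t%d", g$id, j)
      m <- g$isoforms[[j]]
      lines <- c(lines, sprintf("%s\t.\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                                seqid, min(m), max(m), g$strand, tid, g$id))
      for (r in seq_len(nrow(m)))
        lines <- c(lines, sprintf("%s\t.\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
                                  seqid, m[r, 1], m[r, 2], g$strand, tid, r, tid))
    }
  }
  writeLines(lines, path)
  path
}
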