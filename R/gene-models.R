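# Gene models, tagging-site choice and clone suitability.
#
# Internal coordinates are 0-based half-open throughout; GFF3 (1-based,
# closed) is converted at the I/O boundary. CDS segments include the stop
# codon, following the GFF3 convention.

#' Construct an isoform
#'
#' @param isoform_id identifier.
#' @param cds_segments two-column matrix (start, end) of 0-based half-open
#'   CDS intervals in genomic coordinates; will be sorted.
#' @param strand "+" or "-".
#' @param utr3 optional 0-based half-open 3'-UTR interval.
#' @return a list of class `isoform` with `stop_codon_pos` set to the
#'   coordinate of the 3'-most CDS base with respect to strand.
#' @export
isoform <- function(isoform_id, cds_segments, strand, utr3 = NULL) {
  m <- matrix(as.integer(cds_segments), ncol = 2,
              dimnames = list(NULL, c("start", "end")))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (any(m[, 2] <= m[, 1])) stop("isoform ", isoform_id, ": empty CDS segment")
  if (nrow(m) > 1 && any(m[-1, 1] < m[-nrow(m), 2]))
    stop("isoform ", isoform_id, ": overlapping CDS segments")
  stop_pos <- unname(if (strand == "+") m[nrow(m), 2] - 1L else m[1, 1])
  structure(list(isoform_id = isoform_id, cds_segments = m, strand = strand,
                 stop_codon_pos = stop_pos, utr3 = utr3),
            class = "isoform")
}

cds_length <- function(iso) sum(iso$cds_segments[, 2] - iso$cds_segments[, 1])

#' Construct a gene model
#'
#' @param gene_id identifier.
#' @param strand "+" or "-".
#' @param isoforms list of [isoform()] objects on the same strand.
#' @param ref reference sequence name.
#' @return a list of class `gene_model`; `frame_ok` is `FALSE` when any
#'   isoform's total CDS length is not divisible by 3 (such genes are
#'   excluded from tagging design with a logged reason).
#' @export
gene_model <- function(gene_id, strand, isoforms, ref = "chr") {
  stopifnot(strand %in% c("+", "-"), length(isoforms) >= 1)
  frame_ok <- all(vapply(isoforms, cds_length, 0L) %% 3L == 0L)
  structure(list(gene_id = gene_id, strand = strand, ref = ref,
                 isoforms = isoforms, frame_ok = frame_ok),
            class = "gene_model")
}

#' Construct a fosmid clone record
#'
#' @param clone_id identifier.
#' @param interval 0-based half-open genomic interval covered by the clone.
#' @param sequence clone nucleotide sequence (may be `NULL` for
#'   coverage-only analyses); when given its length must equal the
#'   interval length.
#' @param ref reference sequence name.
#' @return a list of class `fosmid_clone`.
#' @export
fosmid_clone <- function(clone_id, interval, sequence = NULL, ref = "chr") {
  interval <- iv(interval[1], interval[2])
  if (!is.null(sequence) && nchar(sequence) != iv_len(interval))
    stop("clone ", clone_id, ": sequence length != interval length")
  structure(list(clone_id = clone_id, interval = interval,
                 sequence = sequence, ref = ref),
            class = "fosmid_clone")
}

gene_span <- function(gene) {
  lo <- min(vapply(gene$isoforms, function(i)
    min(i$cds_segments[, 1], if (is.null(i$utr3)) Inf else i$utr3[1]), 0))
  hi <- max(vapply(gene$isoforms, function(i)
    max(i$cds_segments[, 2], if (is.null(i$utr3)) -Inf else i$utr3[2]), 0))
  c(lo, hi)
}

#' Parse gene models from a GFF3 file
#'
#' Reads gene/mRNA/CDS (and optional three_prime_UTR) features and returns
#' gene models in internal 0-based half-open coordinates. Genes with an
#' isoform whose CDS length is not divisible by 3 are kept with
#' `frame_ok = FALSE` and reported in the `warnings` attribute rather than
#' silently dropped.
#'
#' @param path GFF3 file path.
#' @return list of `gene_model`; attribute `warnings` is a data.frame of
#'   frame complaints (possibly empty).
#' @export
parse_gff <- function(path) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  warn <- data.frame(gene_id = character(0), isoform_id = character(0),
                     cds_len = integer(0))
  if (length(gr) == 0) {
    out <- list()
    attr(out, "warnings") <- warn
    return(out)
  }
  df <- as.data.frame(gr)
  df$Parent <- vapply(df$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  tx <- df[df$type %in% c("mRNA", "transcript"), ]
  cds <- df[df$type == "CDS", ]
  utr <- df[df$type == "three_prime_UTR", ]
  genes <- list()
  for (gid in unique(tx$Parent)) {
    tset <- tx[tx$Parent == gid, ]
    isos <- list()
    for (j in seq_len(nrow(tset))) {
      tid <- tset$ID[j]
      cseg <- cds[cds$Parent == tid, ]
      if (nrow(cseg) == 0) next
      u <- utr[utr$Parent == tid, ]
      u3 <- if (nrow(u)) iv(min(u$start) - 1L, max(u$end)) else NULL
      isos[[length(isos) + 1L]] <-
        isoform(tid, cbind(cseg$start - 1L, cseg$end), tset$strand[j], utr3 = u3)
    }
    if (!length(isos)) next
    gm <- gene_model(gid, as.character(tset$strand[1]), isos,
                     ref = as.character(tset$seqnames[1]))
    if (!gm$frame_ok) {
      bad <- Filter(function(i) cds_length(i) %% 3L != 0L, isos)
      warn <- rbind(warn, data.frame(
        gene_id = gid,
        isoform_id = vapply(bad, `[[`, "", "isoform_id"),
        cds_len = vapply(bad, cds_length, 0L)))
    }
    genes[[gid]] <- gm
  }
  attr(genes, "warnings") <- warn
  genes
}

#' Choose the tagging site of a gene
#'
#' The tag is placed at the most commonly used C-terminus over the gene's
#' isoforms: the stop-codon position shared by the largest number of
#' isoforms. Ties are broken towards the 3'-most stop with respect to
#' strand and flagged.
#'
#' @param gene a `gene_model`.
#' @return list with `gene_id`, `strand`, `stop_pos` (coordinate of the
#'   3'-most CDS base of the chosen terminus), `insertion_point` (0-based
#'   genomic coordinate immediately 5' of the stop codon in coding
#'   orientation), `stop_interval` (the stop-codon triplet), `tie`
#'   (logical) and `n_supporting` isoforms.
#' @export
tag_site <- function(gene) {
  stopifnot(length(gene$isoforms) >= 1)
  stops <- vapply(gene$isoforms, `[[`, 0L, "stop_codon_pos")
  tab <- table(stops)
  best <- max(tab)
  cand <- as.integer(names(tab)[tab == best])
  tie <- length(cand) > 1L
  chosen <- if (gene$strand == "+") max(cand) else min(cand)
  if (gene$strand == "+") {
    stop_iv <- iv(chosen - 2L, chosen + 1L)   # stop codon triplet
    ip <- chosen - 2L                          # insert before the stop codon
  } else {
    stop_iv <- iv(chosen, chosen + 3L)
    ip <- chosen + 3L                          # genomically after the triplet
  }
  list(gene_id = gene$gene_id, strand = gene$strand, stop_pos = chosen,
       insertion_point = ip, stop_interval = stop_iv,
       tie = tie, n_supporting = as.integer(best))
}

#' Select a suitable fosmid clone for a gene
#'
#' A clone is suitable when its interval contains the annotated gene span
#' with at least `min_flank` bases on both sides. Among qualifying clones
#' the one maximizing the smaller flank is returned; ties break
#' lexicographically by clone id.
#'
#' @param gene a `gene_model`.
#' @param clones list of `fosmid_clone`.
#' @param min_flank minimum flank on each side in bases (default 2500).
#' @return the selected `fosmid_clone`, or `NULL` when none qualifies.
#' @export
select_fosmid <- function(gene, clones, min_flank = 2500L) {
  clones <- Filter(function(cl) cl$ref == gene$ref, clones)
  if (!length(clones)) return(NULL)
  span <- gene_span(gene)
  up <- vapply(clones, function(cl) span[1] - cl$interval[[1]], 0)
  dn <- vapply(clones, function(cl) cl$interval[[2]] - span[2], 0)
  ok <- up >= min_flank & dn >= min_flank
  if (!any(ok)) return(NULL)
  minfl <- pmin(up, dn)
  ids <- vapply(clones, `[[`, "", "clone_id")
  o <- order(-minfl, ids)
  sel <- o[ok[o]][1]
  res <- clones[[sel]]
  stopifnot(span[1] - res$interval[[1]] >= min_flank,
            res$interval[[2]] - span[2] >= min_flank)
  res
}

#' Fraction of genes covered by a suitable clone
#'
#' @param genes list of `gene_model`.
#' @param clones list of `fosmid_clone`.
#' @param min_flank minimum flank (default 2500).
#' @return list with `covered`, `total`, `fraction` and `percent`
#'   (half-up, 1 decimal).
#' @export
coverage_stats <- function(genes, clones, min_flank = 2500L) {
  if (!length(genes)) stop("coverage_stats: empty gene list")
  covered <- sum(vapply(genes, function(g)
    !is.null(select_fosmid(g, clones, min_flank)), TRUE))
  frac <- covered / length(genes)
  list(covered = covered, total = length(genes), fraction = frac,
       percent = round_half_up(100 * frac, 1))
}

#' Is the gene's ORF encoded within a single exon?
#'
#' `TRUE` iff every isoform's CDS consists of exactly one segment.
#'
#' @param gene a `gene_model`.
#' @return logical.
#' @export
is_single_exon_cds <- function(gene) {
  all(vapply(gene$isoforms, function(i) nrow(i$cds_segments) == 1L, TRUE))
}

#' Does the gene have alternative C-termini?
#'
#' `TRUE` iff the isoforms use two or more distinct stop-codon positions.
#'
#' @param gene a `gene_model`.
#' @return logical.
#' @export
has_alternative_c_termini <- function(gene) {
  length(unique(vapply(gene$isoforms, `[[`, 0L, "stop_codon_pos"))) >= 2L
}

#' Write a per-gene design report
#'
#' TSV report of clone selection and gene-model classifications for a set
#' of genes.
#'
#' @param genes list of `gene_model`.
#' @param clones list of `fosmid_clone`.
#' @param path output TSV path.
#' @param min_flank minimum flank (default 2500).
#' @return invisibly, the report data.frame.
#' @export
write_design_report <- function(genes, clones, path, min_flank = 2500L) {
  rows <- lapply(genes, function(g) {
    sel <- if (g$frame_ok) select_fosmid(g, clones, min_flank) else NULL
    ts <- tag_site(g)
    data.frame(
      gene_id = g$gene_id, strand = g$strand,
      frame_ok = g$frame_ok,
      clone_id = if (is.null(sel)) NA_character_ else sel$clone_id,
      covered = !is.null(sel),
      tag_insertion_point = ts$insertion_point,
      tag_tie = ts$tie,
      single_exon_cds = is_single_exon_cds(g),
      alternative_c_termini = has_alternative_c_termini(g),
      note = if (!g$frame_ok) "excluded: CDS length not divisible by 3" else ""
    )
  })
  rep <- do.call(rbind, rows)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
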