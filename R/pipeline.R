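# Staged workflows (design -> simulate -> validate -> report) behind the
# command-line interface. All thresholds are echoed into a machine-readable
# run log so every run is reproducible from its outputs.

# lightweight construct record for file-based workflows
construct_stub <- function(clone_id, gene_id, seq, tag_lo, tag_hi, tag_strand,
                           cassette) {
  structure(list(base = list(clone_id = clone_id), gene_id = gene_id,
                 state = "tagged_flipped", seq = seq,
                 tag_interval = iv(tag_lo, tag_hi), tag_strand = tag_strand,
                 edit_log = list(), cassette = cassette),
            class = "engineered_construct")
}

#' Read clones from a FASTA file
#'
#' Each record is one fosmid clone; the description may carry
#' `ref=<name> start=<0-based offset>` fields, otherwise the clone sits at
#' offset 0 of a reference named after the record.
#'
#' @param path FASTA path.
#' @return list of `fosmid_clone`.
#' @export
read_clones_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(ss), function(i) {
    full <- names(ss)[i]
    id <- strsplit(full, "\\s+")[[1]][1]
    kv <- regmatches(full, gregexpr("[a-z]+=[^ ]+", full))[[1]]
    kvl <- stats::setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
    start <- if ("start" %in% names(kvl)) as.integer(kvl[["start"]]) else 0L
    ref <- if ("ref" %in% names(kvl)) kvl[["ref"]] else id
    fosmid_clone(id, c(start, start + Biostrings::width(ss)[i]),
                 as.character(ss[[i]]), ref = ref)
  })
}

write_construct_meta <- function(constructs, path) {
  meta <- data.frame(
    clone_id = vapply(constructs, function(x) x$base$clone_id, ""),
    gene_id = vapply(constructs, `[[`, "", "gene_id"),
    tag_lo = vapply(constructs, function(x) x$tag_interval[[1]], 0L),
    tag_hi = vapply(constructs, function(x) x$tag_interval[[2]], 0L),
    tag_strand = vapply(constructs, `[[`, "", "tag_strand"))
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(meta)
}

read_constructs <- function(fasta, meta_tsv, cassette = tag_cassette()) {
  ss <- Biostrings::readDNAStringSet(fasta)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1)
  meta <- utils::read.delim(meta_tsv, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    j <- match(meta$clone_id[i], ids)
    if (is.na(j)) stop("construct sequence missing for ", meta$clone_id[i])
    construct_stub(meta$clone_id[i], meta$gene_id[i], as.character(ss[[j]]),
                   meta$tag_lo[i], meta$tag_hi[i], meta$tag_strand[i], cassette)
  })
}

#' Design tagged constructs for all genes in an annotation
#'
#' Parses gene models, picks a suitable fosmid per gene (>= `min_flank` on
#' both sides), runs the two-step tagging pipeline and verifies every
#' construct. Writes the engineered FASTA, construct metadata, edit log and
#' design report into `out_dir`.
#'
#' @param gff GFF3 annotation path.
#' @param fasta clone FASTA path (see [read_clones_fasta()]).
#' @param out_dir output directory.
#' @param cassette a `tag_cassette`.
#' @param min_flank minimum clone flank (default 2500).
#' @param arm_len homology-arm length (default 50).
#' @return list with `constructs`, `failures` (data.frame) and `ok`
#'   (logical: all frame checks passed and no failures).
#' @export
run_design <- function(gff, fasta, out_dir, cassette = tag_cassette(),
                       min_flank = 2500L, arm_len = 50L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genes <- parse_gff(gff)
  clones <- read_clones_fasta(fasta)
  constructs <- list()
  failures <- data.frame(gene_id = character(0), reason = character(0))
  for (g in genes) {
    if (!g$frame_ok) {
      failures <- rbind(failures, data.frame(
        gene_id = g$gene_id, reason = "CDS length not divisible by 3"))
      next
    }
    fos <- select_fosmid(g, clones, min_flank = min_flank)
    if (is.null(fos)) {
      failures <- rbind(failures, data.frame(
        gene_id = g$gene_id, reason = "no suitable fosmid"))
      next
    }
    res <- tryCatch(tag_fosmid(fos, g, cassette, arm_len = arm_len),
                    error = function(e) structure(
                      list(step = NA, gene_id = g$gene_id,
                           reason = conditionMessage(e)),
                      class = "recombineering_failure"))
    if (inherits(res, "recombineering_failure")) {
      failures <- rbind(failures, data.frame(gene_id = g$gene_id,
                                             reason = res$reason))
      next
    }
    if (!res$report$pass) {
      failures <- rbind(failures, data.frame(
        gene_id = g$gene_id,
        reason = paste("frame check failed:",
                       paste(names(res$report$checks)[!res$report$checks],
                             collapse = ","))))
      next
    }
    constructs[[length(constructs) + 1L]] <- res$construct
  }
  if (length(constructs)) {
    write_constructs_fasta(constructs, file.path(out_dir, "constructs.fasta"))
    write_construct_meta(constructs, file.path(out_dir, "constructs.tsv"))
    write_edit_log(constructs, file.path(out_dir, "edit_log.tsv"))
  }
  write_design_report(genes, clones, file.path(out_dir, "design_report.tsv"),
                      min_flank = min_flank)
  if (nrow(failures))
    utils::write.table(failures, file.path(out_dir, "failures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  list(constructs = constructs, failures = failures,
       ok = nrow(failures) == 0L)
}

#' Default run configuration
#'
#' @param ... overrides for the default fields.
#' @return named list covering simulation and validation parameters.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, depth = 50, insert_mean = 3000L, insert_sd = 1000L,
              read_len = 100L, seq_error_rate = 0, dup_rate = 0,
              arm_substitution_rate = 0, junction_error_rate = 0,
              cassette_internal_rate = 0, unflipped_probability = 0,
              indel_rate = 0, max_indel = 3L,
              insert_window = c(2200L, 3700L), min_anchor = 20L,
              min_cov = 3L, min_score = 20, error_rate = 0.01,
              confirm_mode = "support", require_both_pools_unflipped = TRUE,
              roi_pad = 1000L, arm_len = 50L, min_flank = 2500L)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Read a JSON run configuration
#' @param path JSON file; fields override [run_config()] defaults.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

as_validator_config <- function(cfg) {
  validator_config(insert_window = cfg$insert_window,
                   min_anchor = cfg$min_anchor, min_cov = cfg$min_cov,
                   min_score = cfg$min_score, error_rate = cfg$error_rate,
                   confirm_mode = cfg$confirm_mode,
                   require_both_pools_unflipped = cfg$require_both_pools_unflipped,
                   roi_pad = cfg$roi_pad)
}

#' Simulate pooled reads for a plate of constructs
#'
#' Applies the configured defect model once per clone, pools the plate and
#' writes per-pool FASTQ files plus truth tables and a config echo.
#'
#' @param plate_csv plate layout CSV (row, col, clone_id).
#' @param constructs_fasta,constructs_tsv engineered constructs from
#'   [run_design()].
#' @param out_dir output directory.
#' @param cfg a [run_config()] list.
#' @return list with `reads`, `pools`, `instances` and written `files`.
#' @export
run_simulate <- function(plate_csv, constructs_fasta, constructs_tsv, out_dir,
                         cfg = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plate <- read_plate_csv(plate_csv)
  pools <- make_pools(plate)
  constructs <- read_constructs(constructs_fasta, constructs_tsv)
  names(constructs) <- vapply(constructs, function(x) x$base$clone_id, "")
  spec <- defect_spec(cfg$arm_substitution_rate, cfg$junction_error_rate,
                      cfg$cassette_internal_rate, cfg$unflipped_probability,
                      cfg$indel_rate, cfg$max_indel)
  instances <- lapply(constructs, function(con)
    apply_defects(con, spec, derive_seed(cfg$seed, con$base$clone_id, "defects"),
                  arm_len = cfg$arm_len))
  sim <- simulate_plate(pools, instances, depth = cfg$depth,
                        insert_mean = cfg$insert_mean, insert_sd = cfg$insert_sd,
                        read_len = cfg$read_len,
                        seq_error_rate = cfg$seq_error_rate,
                        dup_rate = cfg$dup_rate, roi_pad = cfg$roi_pad,
                        seed = cfg$seed)
  files <- write_pool_fastq(sim$reads, file.path(out_dir, "fastq"))
  truth_mut <- data.table::rbindlist(lapply(names(instances), function(cl) {
    tm <- instances[[cl]]$truth
    if (is.null(tm) || !nrow(tm)) return(NULL)
    cbind(clone_id = cl, tm)
  }))
  if (!is.null(truth_mut) && nrow(truth_mut))
    utils::write.table(truth_mut, file.path(out_dir, "truth_mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(clone_id = names(instances),
               unflipped = vapply(instances, `[[`, TRUE, "unflipped")),
    file.path(out_dir, "truth_unflipped.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_pool_manifest(pools, file.path(out_dir, "pools.tsv"))
  jsonlite::write_json(cfg, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA)
  list(reads = sim$reads, pools = pools, instances = instances, files = files)
}

#' Validate pooled reads against engineered references
#'
#' @param fastq_dir directory of per-pool FASTQ files (simulation mode);
#'   alternatively `sam` may name a SAM file of pre-aligned reads.
#' @param constructs_fasta,constructs_tsv intended constructs.
#' @param plate_csv plate layout CSV.
#' @param out_dir output directory.
#' @param cfg a [run_config()] list.
#' @param sam optional SAM path (real-data mode; `fastq_dir` ignored).
#' @return the `validation_result` (also written as TSV/JSON files).
#' @export
run_validate <- function(fastq_dir, constructs_fasta, constructs_tsv,
                         plate_csv, out_dir, cfg = run_config(), sam = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plate <- read_plate_csv(plate_csv)
  pools <- make_pools(plate)
  constructs <- read_constructs(constructs_fasta, constructs_tsv)
  refs <- reference_set(constructs, constructs[[1]]$cassette,
                        roi_pad = cfg$roi_pad)
  vcfg <- as_validator_config(cfg)
  if (!is.null(sam)) {
    ing <- ingest_sam(sam, refs)
    reads <- ing$reads
    reads[, pool_id := sub(":.*$", "", pair_id)]
    mp <- list(hits = ing$hits, events = ing$events)
    resolved <- resolve_pairs(mp, reads, refs, insert_window = vcfg$insert_window)
    # reuse the standard downstream by emulating validate_pools internals
    result <- validate_from_resolved(resolved, mp, refs, pools, vcfg)
  } else {
    reads <- read_pool_fastq(fastq_dir)
    result <- validate_pools(reads, refs, pools, vcfg)
  }
  utils::write.table(result$verdicts, file.path(out_dir, "verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(result$confirmed)) {
    spect <- mutation_spectrum(result$confirmed, refs, arm_len = cfg$arm_len)
    utils::write.table(spect, file.path(out_dir, "confirmed_variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (nrow(result$calls))
    utils::write.table(result$calls, file.path(out_dir, "calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  s <- result$summary
  jsonlite::write_json(
    list(counts = as.list(s$counts), total = s$total,
         percent = as.list(s$percent)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  result
}

#' Report a library summary from a verdicts table
#'
#' @param verdicts_tsv path to a verdict TSV written by [run_validate()].
#' @param out output path.
#' @param format `"json"` or `"tsv"`.
#' @return invisibly, the `library_summary`.
#' @export
run_report <- function(verdicts_tsv, out, format = c("json", "tsv")) {
  format <- match.arg(format)
  v <- data.table::as.data.table(utils::read.delim(verdicts_tsv,
                                                   stringsAsFactors = FALSE))
  s <- summarize_library(v)
  if (format == "json") {
    jsonlite::write_json(list(counts = as.list(s$counts), total = s$total,
                              percent = as.list(s$percent)),
                         out, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(
      data.frame(category = names(s$counts), count = as.integer(s$counts),
                 percent = as.numeric(s$percent[names(s$counts)])),
      out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(s)
}
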