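# 96-well plates and the 8-row + 12-column pooling design.
#
# Each occupied well contributes its clone to exactly one row pool and one
# column pool; a clone observed in both pools of a well is cross-confirmed.
# Because every fosmid carries a unique genomic insert, clone identity
# inside a pool is resolved by mapping location; deconvolution to wells is
# used to cross-check the two independent observations of the same clone.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

#' Construct a 96-well plate layout
#'
#' @param wells data.frame with columns `row` (A..H), `col` (1..12) and
#'   `clone_id`, one row per occupied well.
#' @param plate_id plate identifier (part of the barcode namespace).
#' @return object of class `plate_layout`.
#' @export
plate_layout <- function(wells, plate_id = "P1") {
  wells <- as.data.frame(wells)
  stopifnot(all(c("row", "col", "clone_id") %in% names(wells)))
  wells$row <- as.character(wells$row)
  wells$col <- as.integer(wells$col)
  if (!all(wells$row %in% PLATE_ROWS)) stop("plate rows must be A..H")
  if (!all(wells$col %in% PLATE_COLS)) stop("plate columns must be 1..12")
  key <- paste(wells$row, wells$col)
  if (anyDuplicated(key)) stop("duplicate well in plate layout")
  if (anyDuplicated(wells$clone_id)) stop("duplicate clone in plate layout")
  if (nrow(wells) > 96L) stop("more than 96 occupied wells")
  structure(list(plate_id = plate_id, wells = wells), class = "plate_layout")
}

#' Pool a plate into 8 row pools and 12 column pools
#'
#' Every occupied well's clone is placed in exactly its row pool and its
#' column pool, each with a distinct barcode. A clone at A1 receives the
#' row-A and column-1 barcodes.
#'
#' @param plate a `plate_layout`.
#' @return object of class `pool_set` with `pools` (data.frame: pool_id,
#'   kind, label, barcode), `membership` (named list pool_id -> clone ids)
#'   and `clone_pools` (data.frame: clone_id, row_pool, col_pool, row, col).
#' @export
make_pools <- function(plate) {
  w <- plate$wells
  row_ids <- paste0(plate$plate_id, ".R", PLATE_ROWS)
  col_ids <- paste0(plate$plate_id, ".C", PLATE_COLS)
  pools <- data.frame(
    pool_id = c(row_ids, col_ids),
    kind = c(rep("row", 8), rep("col", 12)),
    label = c(PLATE_ROWS, as.character(PLATE_COLS)),
    barcode = sprintf("BC%02d.%s", seq_len(20), plate$plate_id)
  )
  membership <- c(
    stats::setNames(lapply(PLATE_ROWS, function(r) w$clone_id[w$row == r]), row_ids),
    stats::setNames(lapply(PLATE_COLS, function(c2) w$clone_id[w$col == c2]), col_ids)
  )
  clone_pools <- data.frame(
    clone_id = w$clone_id,
    row = w$row, col = w$col,
    row_pool = sprintf("%s.R%s", plate$plate_id, w$row),
    col_pool = sprintf("%s.C%d", plate$plate_id, w$col)
  )
  structure(list(plate_id = plate$plate_id, pools = pools,
                 membership = membership, clone_pools = clone_pools),
            class = "pool_set")
}

#' Deconvolve pool evidence to candidate wells
#'
#' Given per-pool positive signals for a single clone-level observation,
#' returns the Cartesian intersection of positive rows and columns; the
#' result is a single well iff exactly one row pool and one column pool are
#' positive.
#'
#' @param evidence named logical or numeric vector (or list) keyed by pool
#'   id (as in `pool_set$pools$pool_id`), or a character vector of positive
#'   pool ids.
#' @param pools the `pool_set`.
#' @return data.frame of candidate wells (`row`, `col`, `well`), possibly
#'   empty.
#' @export
deconvolve <- function(evidence, pools) {
  if (is.character(evidence) && is.null(names(evidence))) {
    pos <- evidence
  } else {
    v <- unlist(evidence)
    pos <- names(v)[as.numeric(v) > 0]
  }
  p <- pools$pools
  rows <- p$label[p$kind == "row" & p$pool_id %in% pos]
  cols <- p$label[p$kind == "col" & p$pool_id %in% pos]
  if (!length(rows) || !length(cols))
    return(data.frame(row = character(0), col = integer(0), well = character(0)))
  g <- expand.grid(row = rows, col = as.integer(cols),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$well <- paste0(g$row, g$col)
  g[order(g$row, g$col), , drop = FALSE]
}

#' Read a plate layout from CSV
#' @param path CSV with columns row, col, clone_id.
#' @param plate_id plate identifier.
#' @return a `plate_layout`.
#' @export
read_plate_csv <- function(path, plate_id = "P1") {
  plate_layout(utils::read.csv(path, stringsAsFactors = FALSE), plate_id = plate_id)
}

#' Write a pool manifest TSV
#' @param pools a `pool_set`.
#' @param path output TSV path.
#' @return invisibly, the manifest data.frame.
#' @export
write_pool_manifest <- function(pools, path) {
  man <- data.frame(
    pool_id = pools$pools$pool_id,
    barcode = pools$pools$barcode,
    members = vapply(pools$membership[pools$pools$pool_id],
                     function(m) paste(m, collapse = ","), "")
  )
  utils::write.table(man, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(man)
}
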