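#' Loop (paired-anchor) tables
#'
#' Chromatin loops -- e.g. PLAC-Seq paired peak regions -- are held as a
#' data.frame with one row per loop: columns `chrom1,start1,end1` (left
#' anchor), `chrom2,start2,end2` (right anchor), `id`, `inter_chrom`
#' (anchors on different chromosomes; retained on load, dropped by
#' [filter_loops()]), `merged_from` (number of source loops combined into
#' this one) and `source_ids` (comma-joined originating ids). Coordinates
#' are 1-based closed in memory, 0-based half-open in BEDPE files. Anchors
#' are ordered so the left anchor starts at or before the right anchor on
#' the same chromosome.
#'
#' @name loop-table
NULL

#' Construct a loop table from anchor coordinates
#'
#' @param chrom1,start1,end1 Left anchor (1-based closed).
#' @param chrom2,start2,end2 Right anchor.
#' @param id Loop ids (generated when `NULL`).
#' @param merged_from,source_ids Merge bookkeeping (see [loop-table]).
#' @return A loop table data.frame.
#' @export
new_loop_table <- function(chrom1, start1, end1, chrom2, start2, end2,
                           id = NULL, merged_from = 1L, source_ids = NULL) {
  n <- length(chrom1)
  if (is.null(id)) id <- sprintf("loop%04d", seq_len(n))
  if (is.null(source_ids)) source_ids <- id
  df <- data.frame(chrom1 = as.character(chrom1), start1 = as.integer(start1),
                   end1 = as.integer(end1), chrom2 = as.character(chrom2),
                   start2 = as.integer(start2), end2 = as.integer(end2),
                   id = as.character(id),
                   inter_chrom = as.character(chrom1) != as.character(chrom2),
                   merged_from = as.integer(rep_len(merged_from, n)),
                   source_ids = as.character(source_ids),
                   stringsAsFactors = FALSE)
  # order anchors so left precedes right on intra-chromosomal loops
  swap <- !df$inter_chrom & df$start2 < df$start1
  if (any(swap)) {
    tmp <- df[swap, c("start1", "end1")]
    df[swap, c("start1", "end1")] <- df[swap, c("start2", "end2")]
    df[swap, c("start2", "end2")] <- tmp
  }
  df
}

anchor_left_gr <- function(loops)
  GenomicRanges::GRanges(loops$chrom1, IRanges::IRanges(loops$start1, loops$end1))

anchor_right_gr <- function(loops)
  GenomicRanges::GRanges(loops$chrom2, IRanges::IRanges(loops$start2, loops$end2))

#' Read loops from a BEDPE file
#'
#' @param path 6+ column BEDPE file (0-based half-open on disk). Column 7, if
#'   present, is taken as the loop id.
#' @return A loop table (see [loop-table]); anchors ordered left-before-right,
#'   inter-chromosomal pairs flagged, not dropped.
#' @export
read_loops_bedpe <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          header = FALSE, comment.char = "#")
  if (ncol(df) < 6L)
    stop("BEDPE must have >= 6 columns, got ", ncol(df), ": ", path)
  id <- if (ncol(df) >= 7L) as.character(df[[7]]) else NULL
  new_loop_table(df[[1]], df[[2]] + 1L, df[[3]],
                 df[[4]], df[[5]] + 1L, df[[6]], id = id)
}

#' Write loops (or CREints) as BEDPE
#'
#' CREint tables carry the extra columns `merged_from` and `promoter_genes`;
#' these are appended after the id column so the file remains valid BEDPE.
#'
#' @param loops Loop or CREint table.
#' @param path Output path.
#' @export
write_loops_bedpe <- function(loops, path) {
  out <- data.frame(loops$chrom1, loops$start1 - 1L, loops$end1,
                    loops$chrom2, loops$start2 - 1L, loops$end2,
                    loops$id)
  if (!is.null(loops$merged_from)) out <- cbind(out, loops$merged_from)
  if (!is.null(loops$promoter_genes)) out <- cbind(out, loops$promoter_genes)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
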