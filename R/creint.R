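#' Filter loops to pairs scorable in one prediction window
#'
#' Drops inter-chromosomal pairs and intra-chromosomal pairs whose anchors
#' are not closer than `max_span` (inner edge to inner edge), so every kept
#' loop fits in the predictor's output window.
#'
#' @param loops Loop table (see [read_loops_bedpe()]).
#' @param max_span Maximum anchor distance in bp (default 900 kb).
#' @return Filtered loop table.
#' @export
filter_loops <- function(loops, max_span = 900000L) {
  if (nrow(loops) == 0L) return(loops)
  gap <- loops$start2 - 1L - loops$end1          # inner-edge distance in bp
  keep <- !loops$inter_chrom & gap < max_span
  loops[keep, , drop = FALSE]
}

anchor_distance_bp <- function(loops) loops$start2 - 1L - loops$end1

#' Merge redundant loops
#'
#' Loops within `radius` of each other are considered redundant: among loops
#' sharing a left anchor (left anchors that overlap or lie within `radius`
#' count as shared), right anchors within `radius` of each other are
#' replaced by their union interval; then the symmetric pass is run on left
#' anchors of loops sharing a right anchor. Identical pairs are collapsed
#' (accumulating `merged_from` and `source_ids`), and the two passes repeat
#' until a fixed point, so merging is idempotent.
#'
#' @param loops Loop table (same-chromosome loops; run [filter_loops()]
#'   first).
#' @param radius Redundancy radius in bp (default 10 kb).
#' @param max_iter Safety cap on merge rounds.
#' @return Merged loop table.
#' @export
merge_redundant_loops <- function(loops, radius = 10000L, max_iter = 25L) {
  if (nrow(loops) == 0L) return(loops)
  if (any(loops$inter_chrom))
    stop("merge_redundant_loops expects intra-chromosomal loops")
  state <- loops
  for (iter in seq_len(max_iter)) {
    before <- loop_signature(state)
    state <- merge_pass(state, radius, side = "right")
    state <- merge_pass(state, radius, side = "left")
    if (identical(loop_signature(state), before)) break
  }
  rownames(state) <- NULL
  state
}

loop_signature <- function(loops)
  paste(loops$chrom1, loops$start1, loops$end1, loops$start2, loops$end2,
        sep = ":", collapse = ";")

# one merge pass: group by the "fixed" anchor (shared = within radius),
# then union the opposite-side anchors that lie within radius of each other
merge_pass <- function(loops, radius, side = c("right", "left")) {
  side <- match.arg(side)
  out <- loops
  for (chr in unique(loops$chrom1)) {
    idx <- which(out$chrom1 == chr)
    if (length(idx) < 2L) next
    sub <- out[idx, , drop = FALSE]
    if (side == "right") {
      grp <- cluster_by_gap(sub$start1, sub$end1, radius)
    } else {
      grp <- cluster_by_gap(sub$start2, sub$end2, radius)
    }
    for (g in unique(grp)) {
      rows <- which(grp == g)
      if (length(rows) < 2L) next
      if (side == "right") {
        cl <- cluster_by_gap(sub$start2[rows], sub$end2[rows], radius)
        for (c2 in unique(cl)) {
          r2 <- rows[cl == c2]
          if (length(r2) < 2L) next
          sub$start2[r2] <- min(sub$start2[r2])
          sub$end2[r2] <- max(sub$end2[r2])
        }
      } else {
        cl <- cluster_by_gap(sub$start1[rows], sub$end1[rows], radius)
        for (c2 in unique(cl)) {
          r2 <- rows[cl == c2]
          if (length(r2) < 2L) next
          sub$start1[r2] <- min(sub$start1[r2])
          sub$end1[r2] <- max(sub$end1[r2])
        }
      }
    }
    out[idx, ] <- sub
  }
  collapse_identical_loops(out)
}

# single-linkage clustering of intervals with inter-interval gap <= radius
cluster_by_gap <- function(start, end, radius) {
  ir <- IRanges::IRanges(start, end)
  red <- IRanges::reduce(ir, min.gapwidth = radius + 1L)
  ov <- IRanges::findOverlaps(ir, red, maxgap = 0L)
  cl <- integer(length(ir))
  cl[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  cl
}

collapse_identical_loops <- function(loops) {
  key <- paste(loops$chrom1, loops$start1, loops$end1, loops$start2,
               loops$end2, sep = ":")
  if (!anyDuplicated(key)) return(loops)
  split_idx <- split(seq_len(nrow(loops)), key)
  rows <- lapply(split_idx, function(i) {
    r <- loops[i[1], , drop = FALSE]
    r$merged_from <- sum(loops$merged_from[i])
    r$source_ids <- paste(unique(unlist(
      strsplit(loops$source_ids[i], ",", fixed = TRUE))), collapse = ",")
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom1, out$start1, out$start2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep loops anchored at promoters of expressed genes (CREints)
#'
#' A loop becomes a putative cis-regulatory element interaction (CREint)
#' when at least one anchor overlaps the promoter -- the strand-aware
#' `promoter_bp` window immediately upstream of the TSS -- of a gene
#' expressed above `min_tpm`. Genes present in the TSS set but absent from
#' the expression table are treated as unexpressed (TPM 0) and reported via
#' a message.
#'
#' @param loops Merged loop table.
#' @param tss 1 bp `GRanges` of TSS positions named by gene id (see
#'   [gene_tss()]).
#' @param expression data.frame with `gene_id`, `tpm`.
#' @param promoter_bp Promoter width upstream of the TSS (default 2 kb).
#' @param min_tpm Expression threshold; genes with `tpm > min_tpm` count
#'   (default 0, i.e. strictly positive expression).
#' @return CREint table: the kept loops with an added `promoter_genes`
#'   column (comma-joined gene ids whose promoter overlaps an anchor).
#' @export
filter_promoter_loops <- function(loops, tss, expression,
                                  promoter_bp = 2000L, min_tpm = 0) {
  if (nrow(loops) == 0L) {
    loops$promoter_genes <- character(0)
    return(loops)
  }
  gene_ids <- names(tss)
  tpm <- expression$tpm[match(gene_ids, expression$gene_id)]
  missing <- gene_ids[is.na(tpm)]
  if (length(missing) > 0L) {
    message(length(missing),
            " gene(s) missing from expression table; treated as TPM 0")
    tpm[is.na(tpm)] <- 0
  }
  expressed <- tss[tpm > min_tpm]
  if (length(expressed) == 0L) {
    out <- loops[integer(0), , drop = FALSE]
    out$promoter_genes <- character(0)
    return(out)
  }
  prom <- GenomicRanges::promoters(expressed, upstream = promoter_bp,
                                   downstream = 0L)
  prom <- GenomicRanges::trim(prom)
  genes_hit <- function(anchors) {
    ov <- GenomicRanges::findOverlaps(anchors, prom)
    split(names(prom)[S4Vectors::subjectHits(ov)],
          factor(S4Vectors::queryHits(ov), levels = seq_len(nrow(loops))))
  }
  hits_l <- genes_hit(anchor_left_gr(loops))
  hits_r <- genes_hit(anchor_right_gr(loops))
  promoter_genes <- mapply(function(a, b)
    paste(sort(unique(c(a, b))), collapse = ","),
    hits_l, hits_r)
  keep <- nzchar(promoter_genes)
  out <- loops[keep, , drop = FALSE]
  out$promoter_genes <- unname(promoter_genes[keep])
  rownames(out) <- NULL
  out
}

#' Pair variants with nearby CREints and compute centering shifts
#'
#' A variant and a CREint are paired when the union span of the variant and
#' both anchors is shorter than `max_span` (so the whole pair fits in the
#' output window) and the variant overlaps neither anchor. The recorded
#' `shift_bp` moves the default variant-centered prediction window so the
#' union span is centered instead.
#'
#' @param variants `GRanges` SV records.
#' @param creints CREint table.
#' @param geometry A [predictor_geometry()] (shift feasibility check).
#' @param max_span Maximum union span in bp (default 900 kb).
#' @return data.frame with `variant_id`, `creint_id`, `shift_bp`,
#'   `union_start`, `union_end`; zero rows if nothing pairs.
#' @export
pair_variant_creints <- function(variants, creints,
                                 geometry = predictor_geometry(),
                                 max_span = 900000L) {
  empty <- data.frame(variant_id = character(), creint_id = character(),
                      shift_bp = integer(), union_start = integer(),
                      union_end = integer(), stringsAsFactors = FALSE)
  if (length(variants) == 0L || nrow(creints) == 0L) return(empty)
  rows <- list()
  left <- anchor_left_gr(creints)
  right <- anchor_right_gr(creints)
  for (i in seq_along(variants)) {
    v <- variants[i]
    same <- which(creints$chrom1 == as.character(seqnames(v)))
    for (j in same) {
      u_start <- min(start(v), creints$start1[j])
      u_end <- max(end(v), creints$end2[j])
      if (u_end - u_start + 1L >= max_span) next
      if (start(v) <= creints$end1[j] && end(v) >= creints$start1[j]) next
      if (start(v) <= creints$end2[j] && end(v) >= creints$start2[j]) next
      union_mid0 <- ((u_start - 1L) + u_end) %/% 2L
      shift <- union_mid0 - sv_midpoint0(v)
      if (abs(shift) >= geometry$input_span_bp / 2) next
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = v$id, creint_id = creints$id[j],
        shift_bp = as.integer(shift),
        union_start = as.integer(u_start), union_end = as.integer(u_end),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score variant-CREint pairs
#'
#' Scores each pair from [pair_variant_creints()] with the prediction window
#' shifted to center the pair. By default the weight track up-weights all
#' CREint anchors falling in the window; `paired_only = TRUE` restricts it
#' to the paired CREint's two anchors.
#'
#' @param pairs Pair table from [pair_variant_creints()].
#' @param variants `GRanges` SV records (must contain every paired variant).
#' @param creints CREint table.
#' @param genome,geometry,predictor,scale,track_metric,augment As in
#'   [score_variant()].
#' @param paired_only Weight only the paired CREint's anchors.
#' @return The pair table with score columns appended (`spearman_score`,
#'   `mse_score`, `unweighted`, `weighted`, `roi_only`).
#' @export
score_variant_creint_pairs <- function(pairs, variants, creints, genome,
                                       geometry = predictor_geometry(),
                                       predictor = "surrogate", scale = 10,
                                       track_metric = "mse",
                                       augment = FALSE,
                                       paired_only = FALSE) {
  all_anchors <- creint_anchor_gr(creints)
  score_cols <- c("spearman_score", "mse_score", "unweighted", "weighted",
                  "roi_only")
  for (col in score_cols) pairs[[col]] <- NA_real_
  for (k in seq_len(nrow(pairs))) {
    v <- variants[variants$id == pairs$variant_id[k]]
    if (length(v) != 1L) stop("pair references unknown variant ",
                              pairs$variant_id[k])
    rois <- if (paired_only) {
      creint_anchor_gr(creints[creints$id == pairs$creint_id[k], ,
                               drop = FALSE])
    } else all_anchors
    sc <- score_variant(v, genome, geometry, predictor, rois = rois,
                        scale = scale, shift_bp = pairs$shift_bp[k],
                        augment = augment, track_metric = track_metric)
    for (col in score_cols) pairs[[col]][k] <- sc[[col]]
  }
  pairs
}

creint_anchor_gr <- function(creints) {
  c(anchor_left_gr(creints), anchor_right_gr(creints))
}

#' Summarize pair scores into one score per variant
#'
#' Each score field becomes the maximum across the variant's pairs; the
#' CREint contributing the weighted maximum is recorded. Variants with zero
#' pairs are absent from the output.
#'
#' @param scored_pairs Output of [score_variant_creint_pairs()].
#' @return data.frame with one row per variant: maxima of each score column,
#'   `n_pairs`, and `best_creint_id`.
#' @export
summarize_variant_scores <- function(scored_pairs) {
  score_cols <- c("spearman_score", "mse_score", "unweighted", "weighted",
                  "roi_only")
  split_rows <- split(seq_len(nrow(scored_pairs)), scored_pairs$variant_id)
  rows <- lapply(names(split_rows), function(vid) {
    i <- split_rows[[vid]]
    out <- data.frame(variant_id = vid, n_pairs = length(i),
                      stringsAsFactors = FALSE)
    for (col in score_cols) {
      vals <- scored_pairs[[col]][i]
      out[[col]] <- if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
    }
    w <- scored_pairs$weighted[i]
    out$best_creint_id <- if (all(is.na(w))) NA_character_
      else scored_pairs$creint_id[i][which.max(w)]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full loop-to-CREint processing chain
#'
#' Convenience wrapper: [filter_loops()], [merge_redundant_loops()],
#' [filter_promoter_loops()].
#'
#' @inheritParams filter_loops
#' @inheritParams merge_redundant_loops
#' @inheritParams filter_promoter_loops
#' @param skip_promoter_filter Keep all merged loops (as for plotting, where
#'   the promoter filter is not applied).
#' @return CREint table.
#' @export
loops_to_creints <- function(loops, tss, expression, max_span = 900000L,
                             radius = 10000L, promoter_bp = 2000L,
                             min_tpm = 0, skip_promoter_filter = FALSE) {
  loops <- filter_loops(loops, max_span)
  loops <- merge_redundant_loops(loops, radius)
  if (skip_promoter_filter) {
    loops$promoter_genes <- rep("", nrow(loops))
    return(loops)
  }
  filter_promoter_loops(loops, tss, expression, promoter_bp, min_tpm)
}
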