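#' Align reference and alternate contact maps
#'
#' After in-silico mutagenesis the two predicted maps cover slightly
#' different genomic material whenever the variant changes sequence length.
#' Alignment restores bin-for-bin comparability: with
#' `b = ceiling(|length_delta| / bin_bp)`, the map of the shorter allele
#' receives `b` masked rows/columns inserted at the variant bin and is then
#' trimmed evenly at both ends back to `n_bins`; for balanced variants
#' (inversions) no padding is needed. All bins overlapping the variant span,
#' plus one guard bin on each side (bins partially overlapping the SV are
#' not comparable), are masked in both maps.
#'
#' @param ref_map,alt_map [contact_map()]s predicted from the two alleles.
#' @param pair The `SequencePair` the maps were predicted from.
#' @param geometry A [predictor_geometry()].
#' @param guard_bins Bins masked on each side of the variant bins.
#' @return An `AlignedMapPair`: `ref_values`/`alt_values` (aligned matrices),
#'   `joint_mask` (per-bin validity), `variant_bins` (masked bin indices),
#'   `diagonal_offset`, `geometry`.
#' @export
align_allele_maps <- function(ref_map, alt_map, pair, geometry,
                              guard_bins = 1L) {
  n <- geometry$n_bins
  bin <- geometry$bin_bp
  crop <- crop_bp(geometry)
  dl <- pair$length_delta
  ref_values <- ref_map$values
  alt_values <- alt_map$values
  mapping <- seq_len(n)

  # changed region in the final frame (the frame of the longer allele's map,
  # which stays untouched): for net deletions that is the reference frame and
  # the changed region is the replaced span; for net insertions it is the
  # alternate frame and the changed region is the replacement
  if (dl > 0L) {
    chg_start <- pair$variant_offset + pair$pad_left   # pad_left <= 0 here
    chg_len <- pair$alt_len
  } else {
    chg_start <- pair$variant_offset
    chg_len <- max(pair$ref_len, 1L)
  }

  if (dl != 0L) {
    # the shorter allele's map is padded at the changed region and trimmed at
    # the window edges: bins left of the change shift by the left-flank
    # padding, bins right of it by the right-flank padding (the two shifts
    # total ceiling(|length_delta| / bin_bp) bins when the variant is
    # bin-aligned); bins straddling the change have no comparable partner
    shift_l <- as.integer(round(abs(pair$pad_left) / bin))
    shift_r <- as.integer(round(abs(pair$pad_right) / bin))
    a <- crop + (seq_len(n) - 1L) * bin               # final-frame bin starts
    mapping <- rep(NA_integer_, n)
    left <- which(a + bin <= chg_start)
    right <- which(a >= chg_start + chg_len)
    mapping[left] <- left + shift_l
    mapping[right] <- right - shift_r
    mapping[!is.na(mapping) & (mapping < 1L | mapping > n)] <- NA_integer_
    if (dl < 0L) {
      alt_values <- index_map(alt_values, mapping)
    } else {
      ref_values <- index_map(ref_values, mapping)
    }
  }

  bs <- floor((chg_start - crop) / bin) + 1L - guard_bins
  be <- floor((chg_start + chg_len - 1 - crop) / bin) + 1L + guard_bins
  variant_bins <- intersect(seq_len(n), seq(bs, be))
  variant_bins <- sort(unique(c(variant_bins, which(is.na(mapping)))))

  joint_mask <- ref_map$mask & alt_map$mask
  joint_mask[variant_bins] <- FALSE
  joint_mask[is.na(mapping)] <- FALSE
  if (!any(joint_mask))
    stop("nothing left to compare: every bin is masked")

  structure(list(ref_values = ref_values, alt_values = alt_values,
                 joint_mask = joint_mask, variant_bins = variant_bins,
                 diagonal_offset = max(ref_map$diagonal_offset,
                                       alt_map$diagonal_offset),
                 geometry = geometry),
            class = "AlignedMapPair")
}

# reindex a square matrix by a bin mapping vector (NA -> masked row/column)
index_map <- function(values, mapping) {
  n <- length(mapping)
  out <- matrix(NA_real_, n, n)
  ok <- which(!is.na(mapping))
  out[ok, ok] <- values[mapping[ok], mapping[ok]]
  out
}

# logical matrix of comparable entries (both bins valid, off-diagonal band,
# both values finite); upper = restrict to i < j
comparable_entries <- function(aligned, upper = TRUE) {
  n <- aligned$geometry$n_bins
  m <- aligned$joint_mask
  ok <- outer(m, m, "&")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ok <- ok & (d >= aligned$diagonal_offset)
  ok <- ok & is.finite(aligned$ref_values) & is.finite(aligned$alt_values)
  if (upper) ok <- ok & upper.tri(matrix(TRUE, n, n))
  ok
}

#' Global disruption scores for an aligned map pair
#'
#' Compares the unmasked upper-triangle entries of the two maps with
#' Spearman's rank correlation (average ranks for ties) and mean squared
#' error. The disruption score `1 - rho` lies in `[0, 2]`.
#'
#' @param aligned An [align_allele_maps()] result.
#' @return List with `spearman_score` (`1 - rho`; `NA` with a `reason` if
#'   either map is constant on the compared entries), `mse_score`, and
#'   `n_entries`.
#' @export
score_global <- function(aligned) {
  ok <- comparable_entries(aligned, upper = TRUE)
  x <- aligned$ref_values[ok]
  y <- aligned$alt_values[ok]
  if (length(x) < 3L)
    return(list(spearman_score = NA_real_, mse_score = NA_real_,
                n_entries = length(x), reason = "fewer than 3 comparable entries"))
  mse <- mean((x - y)^2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(spearman_score = NA_real_, mse_score = mse,
                n_entries = length(x),
                reason = "constant map values; correlation undefined"))
  rho <- stats::cor(x, y, method = "spearman")
  list(spearman_score = 1 - rho, mse_score = mse, n_entries = length(x),
       reason = NA_character_)
}

#' Per-bin disruption track
#'
#' Compares each 1-bin-wide column of the two maps (the vectors
#' `ref(i, j)` vs `alt(i, j)` over comparable partners `i`), giving one
#' disruption value per bin (448 at default geometry). Masked bins, and bins
#' with fewer than 3 comparable partners, carry `NA`.
#'
#' @param aligned An [align_allele_maps()] result.
#' @param metric `"mse"` (default; stable when a column is near-constant) or
#'   `"spearman"` (`1 - rho` per column).
#' @return A `DisruptionTrack`: list with `values` (length `n_bins`),
#'   `metric`, `mask`.
#' @export
disruption_track <- function(aligned, metric = c("mse", "spearman")) {
  metric <- match.arg(metric)
  n <- aligned$geometry$n_bins
  ok <- comparable_entries(aligned, upper = FALSE)
  values <- rep(NA_real_, n)
  if (metric == "mse") {
    d2 <- (aligned$ref_values - aligned$alt_values)^2
    d2[!ok] <- NA_real_
    cnt <- colSums(ok)
    values <- ifelse(cnt >= 3L, colSums(d2, na.rm = TRUE) / cnt, NA_real_)
  } else {
    for (j in seq_len(n)) {
      i <- which(ok[, j])
      if (length(i) < 3L) next
      x <- aligned$ref_values[i, j]; y <- aligned$alt_values[i, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      values[j] <- 1 - stats::cor(x, y, method = "spearman")
    }
  }
  values[!aligned$joint_mask] <- NA_real_
  structure(list(values = values, metric = metric,
                 mask = aligned$joint_mask),
            class = "DisruptionTrack")
}

#' Build a per-bin ROI weight track for a prediction window
#'
#' Bins of the output map whose genomic interval overlaps any region of
#' interest by at least 1 bp get weight `scale`; all other bins get 1.
#'
#' @param rois `GRanges` of regions of interest (may be empty).
#' @param window The [build_prediction_window()] the map was predicted from.
#' @param geometry A [predictor_geometry()].
#' @param scale Weight applied to ROI bins (default 10).
#' @return A `WeightTrack`: list with `values` (length `n_bins`, in
#'   `{1, scale}`) and `scale`.
#' @export
build_weight_track <- function(rois, window, geometry, scale = 10) {
  if (scale <= 0) stop("scale must be positive")
  n <- geometry$n_bins
  out_start0 <- window$start - 1L + crop_bp(geometry)
  bins <- GenomicRanges::GRanges(
    window$chrom,
    IRanges::IRanges(start = out_start0 + (seq_len(n) - 1L) * geometry$bin_bp + 1L,
                     width = geometry$bin_bp))
  w <- rep(1, n)
  if (length(rois) > 0L) {
    hit <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(bins, rois, minoverlap = 1L)))
    w[hit] <- scale
  }
  structure(list(values = w, scale = scale), class = "WeightTrack")
}

#' Summarize a disruption track into a scalar score
#'
#' `weighted` is the weight-normalized mean `sum(d * w) / sum(w)` over
#' unmasked bins (so it reduces exactly to the unweighted mean when all
#' weights are equal, and matches the unweighted score when ROI and non-ROI
#' bins are equally disrupted); `roi_only` is the plain mean over ROI bins
#' (weight > 1); `unweighted` is the plain mean. `normalize = FALSE` gives
#' the unnormalized form `mean(d * w)` instead.
#'
#' @param track A [disruption_track()].
#' @param weights A [build_weight_track()] result (ignored for
#'   `mode = "unweighted"`).
#' @param mode `"weighted"`, `"roi_only"` or `"unweighted"`.
#' @param normalize Divide by the summed weights (default) or not.
#' @return Scalar score (`NA` with a `"reason"` attribute when undefined).
#' @export
weighted_score <- function(track, weights = NULL,
                           mode = c("weighted", "roi_only", "unweighted"),
                           normalize = TRUE) {
  mode <- match.arg(mode)
  d <- track$values
  valid <- !is.na(d)
  if (!any(valid)) {
    out <- NA_real_; attr(out, "reason") <- "no unmasked track bins"
    return(out)
  }
  if (mode == "unweighted") return(mean(d[valid]))
  if (is.null(weights)) stop("mode '", mode, "' needs a weight track")
  w <- weights$values
  if (length(w) != length(d)) stop("track and weight lengths differ")
  if (mode == "roi_only") {
    sel <- valid & w > 1
    if (!any(sel)) {
      out <- NA_real_
      attr(out, "reason") <- "no unmasked ROI bins"
      return(out)
    }
    return(mean(d[sel]))
  }
  if (normalize) sum(d[valid] * w[valid]) / sum(w[valid])
  else mean(d[valid] * w[valid])
}

#' Average scores over augmentation replicates
#'
#' @param records data.frame of per-augmentation score rows (columns
#'   `spearman_score`, `mse_score`, `unweighted`, `weighted`, `roi_only`,
#'   ...).
#' @return One-row data.frame of arithmetic means with `augmentation` set to
#'   `averaged-of-<n>`.
#' @export
average_augmented <- function(records) {
  if (nrow(records) == 0L) stop("no score records to average")
  num <- vapply(records, is.numeric, logical(1))
  out <- records[1, , drop = FALSE]
  for (col in names(records)[num])
    out[[col]] <- mean(records[[col]], na.rm = FALSE)
  out$augmentation <- sprintf("averaged-of-%d", nrow(records))
  out$n_augment <- nrow(records)
  rownames(out) <- NULL
  out
}

#' Score one variant end to end
#'
#' Builds the prediction window (optionally shifted), constructs the allele
#' sequences, predicts both contact maps, aligns them and computes the
#' global and track-based disruption scores. With `augment = TRUE` the four
#' augmentation pairs are scored and averaged; windows clamped at a contig
#' edge are scored unaugmented so the average is never silently biased.
#'
#' @param variant Length-1 `GRanges` SV record.
#' @param genome `DNAStringSet` genome.
#' @param geometry A [predictor_geometry()].
#' @param predictor Registered predictor name or function.
#' @param rois `GRanges` of regions of interest, or `NULL` for no weighting.
#' @param scale ROI up-weighting factor (default 10).
#' @param shift_bp Window shift in bp (e.g. from [pair_variant_creints()]).
#' @param augment Average over the 4 augmentation pairs.
#' @param track_metric Per-bin metric for [disruption_track()].
#' @param predictor_args Extra arguments passed to the predictor.
#' @return One-row data.frame: `variant_id`, `spearman_score`, `mse_score`,
#'   `unweighted`, `weighted`, `roi_only`, `n_augment`, `augmentation`,
#'   `window_clamped`.
#' @export
score_variant <- function(variant, genome, geometry = predictor_geometry(),
                          predictor = "surrogate", rois = NULL, scale = 10,
                          shift_bp = 0L, augment = FALSE,
                          track_metric = "mse", predictor_args = list()) {
  chrom <- as.character(seqnames(variant))
  window <- build_prediction_window(variant, geometry, shift_bp,
                                    length(genome[[chrom]]))
  pair <- construct_allele_sequences(window, genome)
  clamped <- window$clamp_bp != 0L
  pairs <- if (augment && !clamped) {
    make_augmentations(pair, window, genome)
  } else list(pair)

  weights_id <- if (!is.null(rois))
    build_weight_track(rois, window, geometry, scale) else NULL

  rows <- lapply(pairs, function(p) {
    ref_map <- do.call(predict_contact_map,
                       c(list(p$ref_seq, geometry, predictor), predictor_args))
    alt_map <- do.call(predict_contact_map,
                       c(list(p$alt_seq, geometry, predictor), predictor_args))
    aligned <- align_allele_maps(ref_map, alt_map, p, geometry)
    glob <- score_global(aligned)
    track <- disruption_track(aligned, track_metric)
    w <- weights_id
    if (!is.null(w)) {
      if (identical(p$augmentation, "revcomp")) {
        w <- structure(list(values = rev(w$values), scale = w$scale),
                       class = "WeightTrack")
      } else if (grepl("^shift", p$augmentation)) {
        # 1 bp window shift: rebuild against the shifted window
        wshift <- window
        delta <- if (grepl("plus", p$augmentation)) 1L else -1L
        wshift$start <- window$start + delta
        wshift$end <- window$end + delta
        w <- build_weight_track(rois, wshift, geometry, scale)
      }
    }
    data.frame(
      variant_id = variant$id,
      spearman_score = glob$spearman_score,
      mse_score = glob$mse_score,
      unweighted = weighted_score(track, mode = "unweighted"),
      weighted = if (is.null(w)) NA_real_
                 else as.numeric(weighted_score(track, w, "weighted")),
      roi_only = if (is.null(w)) NA_real_
                 else as.numeric(weighted_score(track, w, "roi_only")),
      augmentation = p$augmentation,
      stringsAsFactors = FALSE)
  })
  out <- average_augmented(do.call(rbind, rows))
  out$window_clamped <- clamped
  out
}

#' Tiled 1-bp deletion scan
#'
#' Scores a 1 bp deletion at every position of `region` (unaugmented global
#' `1 - Spearman` score, window centered on the position). Against a
#' boundary-motif predictor, the profile peaks within a disrupted motif,
#' recovering the sequence determinant of the contact change.
#'
#' @param region Length-1 `GRanges` to scan.
#' @param genome `DNAStringSet` genome.
#' @param geometry A [predictor_geometry()].
#' @param predictor Predictor name or function.
#' @param max_scan_bp Guard cap on the region length.
#' @return data.frame with `pos` (1-based) and `score`, one row per
#'   position.
#' @export
tiled_deletion_scan <- function(region, genome,
                                geometry = predictor_geometry(),
                                predictor = "surrogate",
                                max_scan_bp = 10000L) {
  if (width(region) > max_scan_bp)
    stop("region longer than scan cap (", max_scan_bp, " bp)")
  if (is.character(predictor)) predictor <- get_predictor(predictor)
  chrom <- as.character(seqnames(region))
  chrom_len <- length(genome[[chrom]])
  positions <- seq(start(region), end(region))
  scores <- vapply(positions, function(p) {
    v <- GenomicRanges::GRanges(chrom, IRanges::IRanges(p, p))
    v$id <- sprintf("scan_%d", p)
    v$svtype <- "DEL"
    v$alt_sequence <- NA_character_
    window <- build_prediction_window(v, geometry, 0L, chrom_len)
    pair <- construct_allele_sequences(window, genome)
    ref_map <- predict_contact_map(pair$ref_seq, geometry, predictor)
    alt_map <- predict_contact_map(pair$alt_seq, geometry, predictor)
    aligned <- align_allele_maps(ref_map, alt_map, pair, geometry)
    score_global(aligned)$spearman_score
  }, numeric(1))
  data.frame(pos = positions, score = scores)
}
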