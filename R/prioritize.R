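#' Thresholds for the prioritization criteria
#'
#' @param near_asd_bp Maximum distance to an ASD gene (default 500 kb).
#' @param mse_pctl Percentile cap on prediction-vs-experiment MSE (default
#'   85).
#' @param score_pctl Percentile floor on disruption scores (default 65).
#' @param expressed_tpm TPM threshold defining an expressed gene (default
#'   0.5).
#' @param sibling_overlap_frac Reciprocal-overlap fraction defining a
#'   similar sibling variant (default 0.5).
#' @param ctcf_overlap_frac Maximum fraction of a touched CTCF peak the
#'   variant may cover (default 0.5).
#' @return A `CriteriaConfig` list.
#' @export
criteria_config <- function(near_asd_bp = 500000L, mse_pctl = 85,
                            score_pctl = 65, expressed_tpm = 0.5,
                            sibling_overlap_frac = 0.5,
                            ctcf_overlap_frac = 0.5) {
  stopifnot(mse_pctl > 0, mse_pctl < 100, score_pctl > 0, score_pctl < 100,
            sibling_overlap_frac > 0, sibling_overlap_frac <= 1,
            ctcf_overlap_frac > 0, ctcf_overlap_frac <= 1)
  structure(list(near_asd_bp = near_asd_bp, mse_pctl = mse_pctl,
                 score_pctl = score_pctl, expressed_tpm = expressed_tpm,
                 sibling_overlap_frac = sibling_overlap_frac,
                 ctcf_overlap_frac = ctcf_overlap_frac),
            class = "CriteriaConfig")
}

CRITERIA_NAMES <- c(
  "not_on_asd_gene", "no_causal_dnsv", "good_prediction", "no_sibling_dnsv",
  "disrupts_creint", "near_asd_gene", "disruptive",          # required
  "not_on_expressed_gene", "not_on_exn_re", "change_on_creint", "on_ctcf",
  "deletion")                                                # optional
REQUIRED_CRITERIA <- CRITERIA_NAMES[1:7]
OPTIONAL_CRITERIA <- CRITERIA_NAMES[8:12]

#' Linear-interpolation percentile threshold
#'
#' @param scores Numeric scores (non-finite values dropped).
#' @param pctl Percentile in (0, 100).
#' @return The interpolated percentile (type-7 quantile).
#' @export
compute_percentile_thresholds <- function(scores, pctl) {
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) stop("no finite scores to take a percentile of")
  unname(stats::quantile(scores, pctl / 100, type = 7))
}

#' Prediction quality: MSE between a predicted and an experimental map
#'
#' The experimental matrix is cropped and re-binned onto the predicted
#' map's bins (block means over overlapping experimental bins), then the
#' mean squared error is taken over jointly unmasked upper-triangle entries
#' outside the diagonal exclusion band. Both inputs are expected log-scaled.
#'
#' @param predicted A [contact_map()].
#' @param experimental A `DenseContactMatrix` (see [read_contact_matrix()])
#'   whose region covers the predicted window, or a matrix already on the
#'   predicted bins.
#' @param window The [build_prediction_window()] the prediction came from
#'   (needed to place the experimental matrix; optional when `experimental`
#'   is a plain matrix).
#' @return MSE (scalar), or `NA` with a `reason` attribute when fewer than 3
#'   joint entries exist.
#' @export
prediction_quality <- function(predicted, experimental, window = NULL) {
  n <- predicted$geometry$n_bins
  if (is.matrix(experimental)) {
    exp_values <- experimental
  } else {
    if (is.null(window))
      stop("window required to align an experimental DenseContactMatrix")
    exp_values <- rebin_experimental(experimental, window,
                                     predicted$geometry)
  }
  if (!all(dim(exp_values) == c(n, n)))
    stop("experimental matrix is ", nrow(exp_values), " x ",
         ncol(exp_values), ", expected ", n, " x ", n)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  ok <- outer(predicted$mask, predicted$mask, "&") &
    d >= predicted$diagonal_offset & upper.tri(exp_values) &
    is.finite(predicted$values) & is.finite(exp_values)
  if (sum(ok) < 3L) {
    out <- NA_real_
    attr(out, "reason") <- "fewer than 3 joint unmasked entries"
    return(out)
  }
  mean((predicted$values[ok] - exp_values[ok])^2)
}

# average an experimental matrix onto the predicted output bins
rebin_experimental <- function(experimental, window, geometry) {
  n <- geometry$n_bins
  out_start0 <- window$start - 1L + crop_bp(geometry)
  exp_start0 <- start(experimental$region) - 1L
  # experimental bin indices overlapping each predicted bin
  groups <- lapply(seq_len(n), function(k) {
    lo0 <- out_start0 + (k - 1L) * geometry$bin_bp
    hi0 <- lo0 + geometry$bin_bp
    i0 <- floor((lo0 - exp_start0) / experimental$bin_bp)
    i1 <- ceiling((hi0 - exp_start0) / experimental$bin_bp) - 1L
    idx <- seq(i0, i1) + 1L
    idx[idx >= 1L & idx <= nrow(experimental$values)]
  })
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      block <- experimental$values[groups[[i]], groups[[j]], drop = FALSE]
      v <- mean(block[is.finite(block)])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Is there a similar sibling variant?
#'
#' A sibling variant is similar when the overlap exceeds `frac` of the
#' proband variant's length AND `frac` of the sibling variant's length
#' (reciprocal-overlap rule).
#'
#' @param proband_sv Length-1 `GRanges`.
#' @param sibling_svs `GRanges` of sibling variants.
#' @param frac Overlap fraction (default 0.5).
#' @return `TRUE` if a similar sibling variant exists.
#' @export
sibling_similarity <- function(proband_sv, sibling_svs, frac = 0.5) {
  if (length(sibling_svs) == 0L) return(FALSE)
  ov <- GenomicRanges::findOverlaps(proband_sv, sibling_svs)
  if (length(ov) == 0L) return(FALSE)
  sib <- sibling_svs[S4Vectors::subjectHits(ov)]
  inter <- GenomicRanges::pintersect(rep(proband_sv, length(sib)), sib)
  wov <- width(inter)
  any(wov > frac * width(proband_sv) & wov > frac * width(sib))
}

#' Evaluate the 12 prioritization criteria for one variant
#'
#' Required criteria: (1) variant does not overlap an ASD-gene exon; (2) the
#' variant's subject has no dnSV overlapping an ASD-gene exon; (3)
#' prediction-vs-experiment MSE below the 85th percentile of MSE across all
#' scored variants; (4) no similar sibling variant; (5) ROI-only CREint
#' score above the 65th percentile of all standard (global 1 - correlation)
#' scores; (6) within 500 kb of an ASD gene; (7) global disruption score
#' above the 65th percentile of all scores. Optional: (8) no overlap with
#' exons of expressed genes (TPM > 0.5); (9) no overlap with ExN regulatory
#' peaks (H3K27Ac, H3K4me1, H3K27me3); (10) weighted score above unweighted
#' score; (11) every touched CTCF peak is covered over less than half its
#' length (the variant clips but does not swallow a CTCF site); (12) the
#' variant is a deletion. Criteria whose inputs are missing are returned as
#' `NA` (unevaluable), never silently passed.
#'
#' @param variant Length-1 `GRanges` SV record.
#' @param context List of evaluation inputs: `scores` (named numeric for
#'   this variant: `global`, `weighted`, `unweighted`, `roi_only`,
#'   `prediction_mse`), `all_global_scores` and `all_prediction_mse`
#'   (numeric vectors across all scored variants, for the percentiles),
#'   `asd_gene_exons`, `asd_genes` (`GRanges`), `subject_variants`
#'   (`GRanges` of all dnSVs of this subject), `sibling_svs` (`GRanges`),
#'   `expressed_exons` (`GRanges` of exons with a `tpm` column or
#'   pre-filtered), `re_peaks` (`GRanges`, ExN regulatory peaks),
#'   `ctcf_peaks` (`GRanges`).
#' @param config A [criteria_config()].
#' @return data.frame with 12 rows: `variant_id`, `criterion`, `required`,
#'   `passed` (logical, `NA` = unevaluable), `evidence`.
#' @export
evaluate_criteria <- function(variant, context, config = criteria_config()) {
  res <- list()
  add <- function(criterion, passed, evidence)
    res[[criterion]] <<- data.frame(
      variant_id = variant$id, criterion = criterion,
      required = criterion %in% REQUIRED_CRITERIA,
      passed = passed, evidence = evidence, stringsAsFactors = FALSE)
  overlaps_any <- function(gr) {
    if (is.null(gr)) return(NA)
    length(GenomicRanges::findOverlaps(variant, gr)) > 0L
  }

  # 1 Not on ASD gene
  hit <- overlaps_any(context$asd_gene_exons)
  add("not_on_asd_gene",
      if (is.na(hit)) NA else !hit,
      if (is.na(hit)) "asd_gene_exons missing"
      else if (hit) "variant overlaps an ASD gene exon"
      else "no ASD gene exon overlap")

  # 2 No causal dnSV elsewhere in this subject
  if (is.null(context$subject_variants) || is.null(context$asd_gene_exons)) {
    add("no_causal_dnsv", NA, "subject_variants or asd_gene_exons missing")
  } else {
    n_hit <- length(GenomicRanges::findOverlaps(context$subject_variants,
                                                context$asd_gene_exons))
    add("no_causal_dnsv", n_hit == 0L,
        sprintf("%d subject dnSV(s) on ASD gene exons", n_hit))
  }

  # 3 Good prediction
  mse <- context$scores[["prediction_mse"]]
  if (is.null(mse) || !is.finite(mse) ||
      length(context$all_prediction_mse) < 2L) {
    add("good_prediction", NA, "prediction MSE unavailable")
  } else {
    thr <- compute_percentile_thresholds(context$all_prediction_mse,
                                         config$mse_pctl)
    add("good_prediction", mse < thr,
        sprintf("MSE %.4g vs P%g = %.4g", mse, config$mse_pctl, thr))
  }

  # 4 No similar sibling dnSV
  if (is.null(context$sibling_svs)) {
    add("no_sibling_dnsv", NA, "sibling_svs missing")
  } else {
    sim <- sibling_similarity(variant, context$sibling_svs,
                              config$sibling_overlap_frac)
    add("no_sibling_dnsv", !sim,
        if (sim) "similar sibling variant found" else "no similar sibling variant")
  }

  # 5 Disrupts CREint
  roi <- context$scores[["roi_only"]]
  if (is.null(roi) || !is.finite(roi) ||
      length(context$all_global_scores) < 2L) {
    add("disrupts_creint", NA, "CREint score unavailable")
  } else {
    thr <- compute_percentile_thresholds(context$all_global_scores,
                                         config$score_pctl)
    add("disrupts_creint", roi > thr,
        sprintf("ROI-only %.4g vs P%g of standard scores = %.4g", roi,
                config$score_pctl, thr))
  }

  # 6 Near ASD gene
  if (is.null(context$asd_genes)) {
    add("near_asd_gene", NA, "asd_genes missing")
  } else if (length(context$asd_genes) == 0L) {
    add("near_asd_gene", FALSE, "no ASD genes on record")
  } else {
    d <- GenomicRanges::distanceToNearest(variant, context$asd_genes)
    dd <- if (length(d) == 0L) Inf else S4Vectors::mcols(d)$distance
    add("near_asd_gene", dd <= config$near_asd_bp,
        sprintf("distance to nearest ASD gene: %s bp", format(dd)))
  }

  # 7 Disruptive
  glob <- context$scores[["global"]]
  if (is.null(glob) || !is.finite(glob) ||
      length(context$all_global_scores) < 2L) {
    add("disruptive", NA, "global score unavailable")
  } else {
    thr <- compute_percentile_thresholds(context$all_global_scores,
                                         config$score_pctl)
    add("disruptive", glob > thr,
        sprintf("global %.4g vs P%g = %.4g", glob, config$score_pctl, thr))
  }

  # 8 Not on expressed gene exon
  hit <- overlaps_any(context$expressed_exons)
  add("not_on_expressed_gene",
      if (is.na(hit)) NA else !hit,
      if (is.na(hit)) "expressed_exons missing"
      else if (hit) "variant overlaps an expressed gene exon"
      else "no expressed exon overlap")

  # 9 Not on ExN regulatory element
  hit <- overlaps_any(context$re_peaks)
  add("not_on_exn_re",
      if (is.na(hit)) NA else !hit,
      if (is.na(hit)) "re_peaks missing"
      else if (hit) "variant overlaps an ExN regulatory peak"
      else "no regulatory peak overlap")

  # 10 Change concentrated on CREints
  w <- context$scores[["weighted"]]; u <- context$scores[["unweighted"]]
  if (is.null(w) || is.null(u) || !is.finite(w) || !is.finite(u)) {
    add("change_on_creint", NA, "weighted/unweighted scores unavailable")
  } else {
    add("change_on_creint", w > u,
        sprintf("weighted %.4g vs unweighted %.4g", w, u))
  }

  # 11 On CTCF (clips, never swallows, any touched CTCF peak)
  if (is.null(context$ctcf_peaks)) {
    add("on_ctcf", NA, "ctcf_peaks missing")
  } else {
    ov <- GenomicRanges::findOverlaps(variant, context$ctcf_peaks)
    if (length(ov) == 0L) {
      add("on_ctcf", TRUE, "no CTCF peak touched")
    } else {
      peaks <- context$ctcf_peaks[S4Vectors::subjectHits(ov)]
      inter <- GenomicRanges::pintersect(rep(variant, length(peaks)), peaks)
      frac <- width(inter) / width(peaks)
      add("on_ctcf", all(frac < config$ctcf_overlap_frac),
          sprintf("max covered fraction of a touched CTCF peak: %.2f",
                  max(frac)))
    }
  }

  # 12 Deletion
  add("deletion", variant$svtype == "DEL",
      paste("svtype =", variant$svtype))

  out <- do.call(rbind, res[CRITERIA_NAMES])
  rownames(out) <- NULL
  out
}

#' Enrichment of CREints near variants over 1 Mb genome bins
#'
#' Tiles each chromosome into `bin_bp` bins (last partial bin kept), flags
#' each bin for overlap with any variant and with any CREint anchor, and
#' tests independence with Pearson's chi-squared (1 df, no continuity
#' correction).
#'
#' @param variants `GRanges` SV records.
#' @param creints CREint table.
#' @param genome_sizes Named vector of chromosome lengths in bp.
#' @param bin_bp Bin size (default 1 Mb).
#' @return List of class `EnrichmentResult`: `contingency` (2x2, rows = SV
#'   overlap yes/no, cols = CREint overlap yes/no), `chi2`, `p`,
#'   `odds_ratio`; statistics are `NA` with a `reason` when a margin is
#'   zero.
#' @export
enrichment_chisq_1mb <- function(variants, creints, genome_sizes,
                                 bin_bp = 1000000L) {
  tiles <- unlist(GenomicRanges::tileGenome(genome_sizes,
                                            tilewidth = bin_bp))
  sv_hit <- GenomicRanges::countOverlaps(tiles, variants) > 0L
  anchors <- creint_anchor_gr(creints)
  cre_hit <- GenomicRanges::countOverlaps(tiles, anchors) > 0L
  tab <- matrix(c(sum(sv_hit & cre_hit), sum(sv_hit & !cre_hit),
                  sum(!sv_hit & cre_hit), sum(!sv_hit & !cre_hit)),
                nrow = 2, byrow = TRUE,
                dimnames = list(sv = c("yes", "no"),
                                creint = c("yes", "no")))
  res <- chisq_2x2(tab)
  structure(c(list(contingency = tab), res), class = "EnrichmentResult")
}

# closed-form Pearson chi-squared for a 2x2 table, 1 df, no Yates correction
chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(list(chi2 = NA_real_, p = NA_real_, odds_ratio = NA_real_,
                reason = "zero margin; chi-squared undefined"))
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       odds_ratio = (a * d) / (b * c), reason = NA_character_)
}

#' Cohort score comparison within variant-length quantiles
#'
#' Computes `n_quantiles` length-quantile cutoffs on the pooled length
#' distribution (linear interpolation), assigns each variant to a quantile,
#' and runs a two-sided Mann-Whitney U test of proband vs sibling score
#' distributions per quantile -- optionally further stratified by a CTCF
#' overlap flag.
#'
#' @param scores data.frame with columns `cohort` (`proband`/`sibling`),
#'   `length`, `score`, and optionally `ctcf_overlap` (logical).
#' @param n_quantiles Number of length quantiles (default 4).
#' @param by_ctcf Also stratify by `ctcf_overlap`.
#' @return List with `cutoffs` and `tests` (data.frame: one row per stratum
#'   with group sizes, `U`, `p`, and a `skipped` reason when a group has
#'   fewer than 2 variants).
#' @export
cohort_length_quantile_test <- function(scores, n_quantiles = 4L,
                                        by_ctcf = FALSE) {
  stopifnot(all(c("cohort", "length", "score") %in% names(scores)))
  probs <- seq_len(n_quantiles - 1L) / n_quantiles
  cutoffs <- unname(stats::quantile(scores$length, probs, type = 7))
  q <- findInterval(scores$length, cutoffs, left.open = TRUE) + 1L
  scores$quantile <- factor(paste0("Q", q),
                            levels = paste0("Q", seq_len(n_quantiles)))
  strata <- if (by_ctcf && "ctcf_overlap" %in% names(scores)) {
    split(scores, list(scores$quantile, scores$ctcf_overlap), drop = FALSE)
  } else split(scores, scores$quantile)
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    pro <- s$score[s$cohort == "proband"]
    sib <- s$score[s$cohort == "sibling"]
    base <- data.frame(stratum = nm, n_proband = length(pro),
                       n_sibling = length(sib), U = NA_real_, p = NA_real_,
                       skipped = NA_character_, stringsAsFactors = FALSE)
    if (length(pro) < 2L || length(sib) < 2L) {
      base$skipped <- "fewer than 2 variants in a group"
      return(base)
    }
    wt <- suppressWarnings(stats::wilcox.test(pro, sib,
                                              alternative = "two.sided"))
    base$U <- unname(wt$statistic)
    base$p <- wt$p.value
    base
  })
  list(cutoffs = cutoffs, tests = do.call(rbind, rows))
}
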