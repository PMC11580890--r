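#' Build (or read) a pipeline run configuration
#'
#' The configuration names every input file, the predictor and geometry, the
#' ROI mode and weighting scale, and the output directory. It can be built
#' programmatically or loaded from a YAML file with the same keys.
#'
#' @param genome FASTA path.
#' @param variants SV table path.
#' @param variants_dialect `"tsv"` or `"vcf"`.
#' @param loops BEDPE path (required for roi = "bedpe" and the pair stage).
#' @param genes,expression,ctcf_peaks,h3k27ac,h3k4me1,h3k27me3,asd_gene_exons,asd_genes
#'   Annotation paths (BED / TSV); `NULL` entries disable the criteria that
#'   need them.
#' @param outdir Output directory.
#' @param predictor Registered predictor name.
#' @param geometry A [predictor_geometry()].
#' @param roi ROI mode: `"none"`, `"bedpe"` (processed loops), `"bed"`
#'   (custom regions from `roi_bed`), or `"genes"` (2 kb windows centered on
#'   every TSS).
#' @param roi_bed BED path for `roi = "bed"`.
#' @param scale ROI up-weighting factor.
#' @param augment Average scores over the 4 augmentation sequences.
#' @param track_metric Per-bin disruption metric (`"mse"` or `"spearman"`).
#' @param criteria A [criteria_config()].
#' @param experimental_map Optional contact-matrix text file for the
#'   prediction-quality criterion.
#' @param scan_region Optional `chrom:start-end` region (1-based) for the
#'   tiled-deletion scan stage.
#' @param seed RNG seed recorded with the run.
#' @param resume Reuse stage outputs that already exist in `outdir`.
#' @return A `RunConfig` list.
#' @export
run_config <- function(genome, variants, variants_dialect = "tsv",
                       loops = NULL, genes = NULL, expression = NULL,
                       ctcf_peaks = NULL, h3k27ac = NULL, h3k4me1 = NULL,
                       h3k27me3 = NULL, asd_gene_exons = NULL,
                       asd_genes = NULL, outdir = "svdisrupt_out",
                       predictor = "surrogate",
                       geometry = predictor_geometry(), roi = "none",
                       roi_bed = NULL, scale = 10, augment = FALSE,
                       track_metric = "mse", criteria = criteria_config(),
                       experimental_map = NULL, scan_region = NULL,
                       seed = 1L, resume = TRUE) {
  if (scale <= 0) stop("scale must be positive")
  cfg <- list(genome = genome, variants = variants,
              variants_dialect = variants_dialect, loops = loops,
              genes = genes, expression = expression,
              ctcf_peaks = ctcf_peaks, h3k27ac = h3k27ac,
              h3k4me1 = h3k4me1, h3k27me3 = h3k27me3,
              asd_gene_exons = asd_gene_exons, asd_genes = asd_genes,
              outdir = outdir, predictor = predictor, geometry = geometry,
              roi = match.arg(roi, c("none", "bedpe", "bed", "genes")),
              roi_bed = roi_bed, scale = scale, augment = augment,
              track_metric = track_metric, criteria = criteria,
              experimental_map = experimental_map,
              scan_region = scan_region, seed = as.integer(seed),
              resume = resume)
  for (key in c("genome", "variants", "loops", "genes", "expression",
                "ctcf_peaks", "h3k27ac", "h3k4me1", "h3k27me3",
                "asd_gene_exons", "asd_genes", "roi_bed",
                "experimental_map")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("configured ", key, " file does not exist: ", p)
  }
  structure(cfg, class = "RunConfig")
}

#' Load a run configuration from YAML
#' @param path YAML file whose keys mirror [run_config()] arguments.
#' @param base_dir Relative input paths are resolved against this directory.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  raw <- yaml::read_yaml(path)
  file_keys <- c("genome", "variants", "loops", "genes", "expression",
                 "ctcf_peaks", "h3k27ac", "h3k4me1", "h3k27me3",
                 "asd_gene_exons", "asd_genes", "roi_bed",
                 "experimental_map")
  for (key in intersect(file_keys, names(raw))) {
    if (!is.null(raw[[key]]) && !startsWith(raw[[key]], "/"))
      raw[[key]] <- file.path(base_dir, raw[[key]])
  }
  if (!is.null(raw$geometry))
    raw$geometry <- do.call(predictor_geometry, raw$geometry)
  if (!is.null(raw$criteria))
    raw$criteria <- do.call(criteria_config, raw$criteria)
  do.call(run_config, raw)
}

PIPELINE_STAGES <- c("score", "pair", "prioritize", "enrich", "cohort",
                     "scan")

stage_outputs <- function(outdir) {
  list(score = file.path(outdir, c("scores.tsv", "exclusions.tsv")),
       pair = file.path(outdir, c("creints.bedpe", "pairs.tsv",
                                  "pair_summary.tsv")),
       prioritize = file.path(outdir, "report.tsv"),
       enrich = file.path(outdir, "enrichment.tsv"),
       cohort = file.path(outdir, "cohort_tests.tsv"),
       scan = file.path(outdir, "scan.tsv"))
}

#' Run the scoring/prioritization pipeline
#'
#' Executes the requested stages in dependency order (`pair`, `prioritize`
#' and `cohort` need `score`; `prioritize` also needs `pair`), writing one
#' TSV per product plus a run log with per-stage counts. With
#' `config$resume`, stages whose outputs already exist are skipped, so
#' re-running an unchanged configuration is cheap and byte-stable.
#'
#' @param config A [run_config()].
#' @param stages Subset of `score`, `pair`, `prioritize`, `enrich`,
#'   `cohort`, `scan`.
#' @return Invisibly, the output directory.
#' @export
run_pipeline <- function(config, stages = c("score", "pair", "prioritize",
                                            "enrich", "cohort")) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outs <- stage_outputs(outdir)
  log_path <- file.path(outdir, "run.log")
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  done <- function(stage) all(file.exists(outs[[stage]]))
  need <- function(stage, dep) {
    if (!done(dep) && !(dep %in% stages))
      stop("stage '", stage, "' needs outputs of stage '", dep,
           "'; run that stage first")
  }
  for (s in intersect(c("pair", "prioritize", "cohort"), stages))
    need(s, "score")
  if ("prioritize" %in% stages) need("prioritize", "pair")

  set.seed(config$seed)
  genome <- read_genome(config$genome)
  variants <- read_sv_records(config$variants, config$variants_dialect)
  geometry <- config$geometry
  ann <- load_pipeline_annotations(config)
  rois <- pipeline_rois(config, ann)

  # dependency order
  for (stage in intersect(PIPELINE_STAGES, stages)) {
    if (config$resume && done(stage)) {
      logmsg("stage %s: outputs present, reused", stage)
      next
    }
    switch(stage,
      score = stage_score(config, genome, variants, geometry, rois, outs,
                          logmsg),
      pair = stage_pair(config, genome, variants, geometry, ann, outs,
                        logmsg),
      prioritize = stage_prioritize(config, genome, variants, geometry,
                                    ann, outs, logmsg),
      enrich = stage_enrich(config, genome, variants, ann, outs, logmsg),
      cohort = stage_cohort(config, variants, ann, outs, logmsg),
      scan = stage_scan(config, genome, geometry, outs, logmsg))
  }
  invisible(outdir)
}

load_pipeline_annotations <- function(config) {
  ann <- list()
  read_bed_or_null <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.size(p) == 0L) return(GenomicRanges::GRanges())
    rtracklayer::import(p, format = "BED")
  }
  for (key in c("ctcf_peaks", "h3k27ac", "h3k4me1", "h3k27me3",
                "asd_gene_exons", "asd_genes", "genes"))
    ann[[key]] <- read_bed_or_null(config[[key]])
  if (!is.null(ann$genes) && length(ann$genes) > 0L)
    names(ann$genes) <- ann$genes$name
  ann$expression <- if (!is.null(config$expression))
    read_expression_table(config$expression) else NULL
  ann$loops <- if (!is.null(config$loops))
    read_loops_bedpe(config$loops) else NULL
  ann
}

pipeline_rois <- function(config, ann) {
  switch(config$roi,
    none = NULL,
    bed = rtracklayer::import(config$roi_bed, format = "BED"),
    genes = {
      if (is.null(ann$genes)) stop("roi = 'genes' needs a gene BED")
      tss <- gene_tss(ann$genes)
      GenomicRanges::trim(GenomicRanges::resize(tss, width = 2000L,
                                                fix = "center"))
    },
    bedpe = {
      if (is.null(ann$loops) || is.null(ann$genes) ||
          is.null(ann$expression))
        stop("roi = 'bedpe' needs loops, genes and expression inputs")
      creints <- loops_to_creints(ann$loops, gene_tss(ann$genes),
                                  ann$expression)
      creint_anchor_gr(creints)
    })
}

pipeline_creints <- function(ann) {
  if (is.null(ann$loops) || is.null(ann$genes) || is.null(ann$expression))
    stop("the pair stage needs loops, genes and expression inputs")
  loops_to_creints(ann$loops, gene_tss(ann$genes), ann$expression)
}

stage_score <- function(config, genome, variants, geometry, rois, outs,
                        logmsg) {
  flt <- apply_exclusion_filters(variants, genome, geometry)
  kept <- flt$kept
  logmsg("stage score: %d variants in, %d kept, %d excluded",
         length(variants), length(kept), nrow(flt$excluded))
  rows <- lapply(seq_along(kept), function(i) {
    v <- kept[i]
    sc <- score_variant(v, genome, geometry, config$predictor, rois = rois,
                        scale = config$scale, augment = config$augment,
                        track_metric = config$track_metric)
    data.frame(variant_id = v$id, cohort = v$cohort, svtype = v$svtype,
               length = width(v), spearman_score = sc$spearman_score,
               mse_score = sc$mse_score, unweighted = sc$unweighted,
               weighted = sc$weighted, roi_only = sc$roi_only,
               n_augment = sc$n_augment, exclusion_code = "",
               stringsAsFactors = FALSE)
  })
  scored <- if (length(rows) > 0L) do.call(rbind, rows) else
    utils::read.table(text = "", col.names = c(
      "variant_id", "cohort", "svtype", "length", "spearman_score",
      "mse_score", "unweighted", "weighted", "roi_only", "n_augment",
      "exclusion_code"))
  utils::write.table(scored, outs$score[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(flt$excluded, outs$score[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("stage score: wrote %d scored rows", nrow(scored))
}

stage_pair <- function(config, genome, variants, geometry, ann, outs,
                       logmsg) {
  creints <- pipeline_creints(ann)
  write_loops_bedpe(creints, outs$pair[1])
  scores <- utils::read.delim(outs$score[1])
  # complex variants are excluded from CREint-weighted analyses
  eligible <- variants[variants$id %in% scores$variant_id &
                       variants$svtype != "CPX"]
  pairs <- pair_variant_creints(eligible, creints, geometry)
  logmsg("stage pair: %d CREints, %d eligible variants, %d pairs",
         nrow(creints), length(eligible), nrow(pairs))
  if (nrow(pairs) > 0L) {
    pairs <- score_variant_creint_pairs(pairs, eligible, creints, genome,
                                        geometry, config$predictor,
                                        config$scale, config$track_metric,
                                        augment = config$augment)
    summary <- summarize_variant_scores(pairs)
  } else {
    summary <- data.frame(variant_id = character(), n_pairs = integer())
  }
  utils::write.table(pairs, outs$pair[2], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(summary, outs$pair[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("stage pair: %d variants summarized", nrow(summary))
}

stage_prioritize <- function(config, genome, variants, geometry, ann, outs,
                             logmsg) {
  scores <- utils::read.delim(outs$score[1])
  summary <- utils::read.delim(outs$pair[3])
  expressed_exons <- prioritize_expressed_exons(ann, config)
  re_peaks <- prioritize_re_peaks(ann)
  sibling_svs <- variants[variants$cohort == "sibling"]
  pro_ids <- scores$variant_id[scores$cohort == "proband"]
  all_global <- scores$spearman_score
  pm <- prediction_mse_all(config, genome, variants, geometry, scores)
  rows <- lapply(pro_ids, function(vid) {
    v <- variants[variants$id == vid]
    srow <- scores[scores$variant_id == vid, ]
    prow <- summary[summary$variant_id == vid, , drop = FALSE]
    ctx <- list(
      scores = list(global = srow$spearman_score,
                    weighted = if (nrow(prow)) prow$weighted else NA_real_,
                    unweighted = if (nrow(prow)) prow$unweighted else NA_real_,
                    roi_only = if (nrow(prow)) prow$roi_only else NA_real_,
                    prediction_mse = pm$per_variant[[vid]] %||% NA_real_),
      all_global_scores = all_global,
      all_prediction_mse = pm$all,
      asd_gene_exons = ann$asd_gene_exons, asd_genes = ann$asd_genes,
      subject_variants = variants[variants$subject_id == v$subject_id],
      sibling_svs = sibling_svs, expressed_exons = expressed_exons,
      re_peaks = re_peaks, ctcf_peaks = ann$ctcf_peaks)
    crit <- evaluate_criteria(v, ctx, config$criteria)
    wide <- as.data.frame(as.list(stats::setNames(crit$passed,
                                                  crit$criterion)))
    wide$variant_id <- vid
    wide$n_required_passed <- sum(crit$passed[crit$required], na.rm = TRUE)
    wide$n_optional_passed <- sum(crit$passed[!crit$required], na.rm = TRUE)
    wide$weighted <- if (nrow(prow)) prow$weighted else NA_real_
    wide
  })
  report <- do.call(rbind, rows)
  if (!is.null(report) && nrow(report) > 0L) {
    ord <- order(-report$n_required_passed,
                 -ifelse(is.na(report$weighted), -Inf, report$weighted))
    report <- report[ord, ]
    report$rank <- seq_len(nrow(report))
    report <- report[, c("variant_id", CRITERIA_NAMES, "n_required_passed",
                         "n_optional_passed", "weighted", "rank")]
  } else {
    report <- data.frame(variant_id = character())
  }
  utils::write.table(report, outs$prioritize, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("stage prioritize: %d proband variants ranked", nrow(report))
}

prioritize_expressed_exons <- function(ann, config) {
  # expressed-gene exons: gene bodies of genes above the TPM cutoff stand in
  # when no exon annotation beyond ASD exons is provided
  if (is.null(ann$genes) || is.null(ann$expression)) return(NULL)
  tpm <- ann$expression$tpm[match(ann$genes$name, ann$expression$gene_id)]
  ann$genes[!is.na(tpm) & tpm > config$criteria$expressed_tpm]
}

prioritize_re_peaks <- function(ann) {
  peaks <- list(ann$h3k27ac, ann$h3k4me1, ann$h3k27me3)
  peaks <- peaks[!vapply(peaks, is.null, logical(1))]
  if (length(peaks) == 0L) return(NULL)
  suppressWarnings(do.call(c, peaks))
}

prediction_mse_all <- function(config, genome, variants, geometry, scores) {
  if (is.null(config$experimental_map))
    return(list(per_variant = list(), all = numeric(0)))
  experimental <- read_contact_matrix(config$experimental_map)
  per <- list()
  for (vid in scores$variant_id) {
    v <- variants[variants$id == vid]
    if (as.character(seqnames(v)) !=
        as.character(seqnames(experimental$region))) next
    window <- build_prediction_window(v, geometry, 0L,
                                      length(genome[[as.character(seqnames(v))]]))
    out_lo <- window$start + crop_bp(geometry)
    out_hi <- window$start - 1L + crop_bp(geometry) + geometry$output_span_bp
    if (out_lo < start(experimental$region) ||
        out_hi > end(experimental$region)) next
    pred <- predict_contact_map(get_sequence(genome,
                                             as.character(seqnames(v)),
                                             window$start, window$end),
                                geometry, config$predictor)
    per[[vid]] <- prediction_quality(pred, experimental, window)
  }
  list(per_variant = per, all = unlist(per, use.names = FALSE))
}

stage_enrich <- function(config, genome, variants, ann, outs, logmsg) {
  creints <- pipeline_creints(ann)
  sizes <- stats::setNames(vapply(names(genome), function(ch)
    length(genome[[ch]]), integer(1)), names(genome))
  rows <- lapply(COHORTS, function(coh) {
    res <- enrichment_chisq_1mb(variants[variants$cohort == coh], creints,
                                sizes)
    data.frame(cohort = coh,
               sv_and_creint = res$contingency[1, 1],
               sv_only = res$contingency[1, 2],
               creint_only = res$contingency[2, 1],
               neither = res$contingency[2, 2],
               chi2 = res$chi2, p = res$p, odds_ratio = res$odds_ratio,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, outs$enrich, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("stage enrich: chi2 %s", paste(round(out$chi2, 3), collapse = "/"))
}

stage_cohort <- function(config, variants, ann, outs, logmsg) {
  scores <- utils::read.delim(outs$score[1])
  df <- data.frame(cohort = scores$cohort, length = scores$length,
                   score = scores$spearman_score,
                   stringsAsFactors = FALSE)
  if (!is.null(ann$ctcf_peaks)) {
    idx <- match(scores$variant_id, variants$id)
    df$ctcf_overlap <- GenomicRanges::countOverlaps(
      variants[idx], ann$ctcf_peaks) > 0L
  }
  res <- cohort_length_quantile_test(df, by_ctcf = "ctcf_overlap" %in%
                                       names(df))
  tests <- res$tests
  tests$cutoffs <- paste(round(res$cutoffs, 1), collapse = ",")
  utils::write.table(tests, outs$cohort, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("stage cohort: %d strata tested", nrow(tests))
}

stage_scan <- function(config, genome, geometry, outs, logmsg) {
  if (is.null(config$scan_region))
    stop("the scan stage needs scan_region = 'chrom:start-end'")
  m <- regmatches(config$scan_region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", config$scan_region))[[1]]
  if (length(m) != 4L) stop("malformed scan_region: ", config$scan_region)
  region <- GenomicRanges::GRanges(m[2],
                                   IRanges::IRanges(as.integer(m[3]),
                                                    as.integer(m[4])))
  prof <- tiled_deletion_scan(region, genome, geometry, config$predictor)
  utils::write.table(prof, outs$scan, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  logmsg("stage scan: %d positions scored", nrow(prof))
}
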