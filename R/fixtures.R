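#' Specification of a synthetic toy dataset
#'
#' Fixes the study conditions every synthetic dataset is generated under:
#' genome size, number of planted boundary motifs, cohort composition, loop
#' and gene counts. All generation is deterministic given `seed`.
#'
#' @param seed RNG seed.
#' @param n_chroms,chrom_bp Number and length of toy chromosomes.
#' @param n_motifs Planted boundary motifs per chromosome.
#' @param n_variants Variants per cohort.
#' @param type_mix Named probabilities over DEL/DUP/INV/CPX.
#' @param len_range Variant length range in bp (log-uniform).
#' @param proband_enrichment Fraction of proband variants placed on a
#'   planted motif (sibling variants are always placed uniformly).
#' @param n_loops Loops per chromosome.
#' @param promoter_fraction Fraction of loops whose left anchor overlaps a
#'   gene promoter.
#' @param n_genes Genes per chromosome.
#' @param tpm_zero_fraction Fraction of genes with zero expression.
#' @param exclusion_showcase Also plant an N-run and append one variant per
#'   exclusion code so filters can be exercised end to end.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chroms = 2L, chrom_bp = 4000000L,
                         n_motifs = 8L, n_variants = 40L,
                         type_mix = c(DEL = 0.5, DUP = 0.2, INV = 0.2,
                                      CPX = 0.1),
                         len_range = c(50L, 100000L),
                         proband_enrichment = 0.8, n_loops = 12L,
                         promoter_fraction = 0.8, n_genes = 30L,
                         tpm_zero_fraction = 0.2,
                         exclusion_showcase = FALSE) {
  stopifnot(chrom_bp >= 1048576L, all(type_mix >= 0), sum(type_mix) > 0,
            n_motifs >= 0L, n_variants >= 0L)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_bp = as.integer(chrom_bp),
                 n_motifs = as.integer(n_motifs),
                 n_variants = as.integer(n_variants),
                 type_mix = type_mix / sum(type_mix),
                 len_range = as.integer(len_range),
                 proband_enrichment = proband_enrichment,
                 n_loops = as.integer(n_loops),
                 promoter_fraction = promoter_fraction,
                 n_genes = as.integer(n_genes),
                 tpm_zero_fraction = tpm_zero_fraction,
                 exclusion_showcase = isTRUE(exclusion_showcase)),
            class = "FixtureSpec")
}

# variants, genes and anchors stay this far from contig ends so 1 Mb
# windows (and pair-centering shifts) never leave the chromosome
FIXTURE_MARGIN_BP <- 600000L

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Generate a toy genome with planted boundary motifs
#'
#' Uniform-random background sequence with the surrogate predictor's
#' boundary motif planted at roughly evenly spaced, jittered positions on
#' random strands. Overlapping plants are re-drawn.
#'
#' @param spec A [fixture_spec()].
#' @param params Surrogate parameters (the motif to plant).
#' @return List with `genome` (`DNAStringSet`) and `motifs` (`GRanges` with
#'   strand).
#' @export
generate_toy_genome <- function(spec, params = surrogate_params()) {
  set.seed(spec$seed)
  motif <- params$motif
  mlen <- nchar(motif)
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  seqs <- character(spec$n_chroms)
  motif_rows <- list()
  lo <- FIXTURE_MARGIN_BP
  hi <- spec$chrom_bp - FIXTURE_MARGIN_BP
  for (ci in seq_len(spec$n_chroms)) {
    s <- random_dna(spec$chrom_bp)
    if (spec$exclusion_showcase && ci == 1L) {
      # 100 kb unknown-sequence run: ~9.5% of any 1 Mb window centered on it
      n_run <- c(3400000L, 3500000L)
      substr(s, n_run[1] + 1L, n_run[2]) <-
        strrep("N", n_run[2] - n_run[1])
    }
    starts <- integer(0)
    if (spec$n_motifs > 0L) {
      anchor_grid <- lo + (seq_len(spec$n_motifs) - 0.5) *
        (hi - lo) / spec$n_motifs
      for (g in anchor_grid) {
        repeat {
          cand <- as.integer(g + sample(-50000L:50000L, 1L))
          if (all(abs(cand - starts) > mlen)) break
        }
        starts <- c(starts, cand)
      }
      strands <- sample(c("+", "-"), spec$n_motifs, replace = TRUE)
      for (k in seq_len(spec$n_motifs)) {
        planted <- if (strands[k] == "+") motif else revcomp_chr(motif)
        substr(s, starts[k], starts[k] + mlen - 1L) <- planted
      }
      motif_rows[[ci]] <- data.frame(chrom = chroms[ci], start = starts,
                                     strand = strands)
    }
    seqs[ci] <- s
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  motifs <- if (length(motif_rows) > 0L) {
    md <- do.call(rbind, motif_rows)
    md <- md[order(md$chrom, md$start), ]
    GenomicRanges::GRanges(md$chrom, IRanges::IRanges(md$start, width = mlen),
                           strand = md$strand)
  } else GenomicRanges::GRanges()
  list(genome = genome, motifs = motifs)
}

#' Generate a two-cohort toy SV callset
#'
#' Proband variants preferentially overlap planted boundary motifs
#' (`proband_enrichment` of them are centered on a random motif); sibling
#' variants are placed uniformly. Types follow `type_mix`; CPX records carry
#' random alternate sequences. With `exclusion_showcase`, one extra variant
#' per exclusion code is appended.
#'
#' @param spec A [fixture_spec()].
#' @param motifs Motif `GRanges` from [generate_toy_genome()].
#' @return `GRanges` of SV records (see [read_sv_records()]).
#' @export
generate_toy_cohort <- function(spec, motifs) {
  set.seed(spec$seed + 1L)
  lo <- FIXTURE_MARGIN_BP
  hi <- spec$chrom_bp - FIXTURE_MARGIN_BP
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  draw_cohort <- function(cohort, on_motif_frac) {
    n <- spec$n_variants
    if (n == 0L)
      return(NULL)
    types <- sample(names(spec$type_mix), n, replace = TRUE,
                    prob = spec$type_mix)
    lens <- as.integer(round(10^stats::runif(
      n, log10(spec$len_range[1]), log10(spec$len_range[2]))))
    on_motif <- stats::runif(n) < on_motif_frac & length(motifs) > 0L
    chrom <- character(n); start <- integer(n)
    for (i in seq_len(n)) {
      if (on_motif[i]) {
        m <- motifs[sample(length(motifs), 1L)]
        chrom[i] <- as.character(seqnames(m))
        center <- (start(m) + end(m)) %/% 2L
        start[i] <- max(lo, center - lens[i] %/% 2L)
      } else {
        chrom[i] <- sample(chroms, 1L)
        start[i] <- sample(lo:(hi - lens[i]), 1L)
      }
    }
    alt <- rep(NA_character_, n)
    cpx <- which(types == "CPX")
    for (i in cpx)
      alt[i] <- random_dna(max(1L, as.integer(round(
        lens[i] * stats::runif(1, 0.5, 1.5)))))
    subject <- sprintf("fam%03d_%s", seq_len(n),
                       if (cohort == "proband") "p" else "s")
    new_sv_records(sprintf("%s_%03d", substr(cohort, 1, 3), seq_len(n)),
                   chrom, start, start + lens - 1L, types, subject, cohort,
                   alt)
  }
  out <- c(draw_cohort("proband", spec$proband_enrichment),
           draw_cohort("sibling", 0))
  if (spec$exclusion_showcase) {
    showcase <- new_sv_records(
      c("excl_unknown_alt", "excl_too_long_abs", "excl_too_long_rel",
        "excl_off_contig", "excl_n_content"),
      rep("chr1", 5),
      c(1000000L, 1000000L, 1000000L, 60L, 3445000L),
      c(1000500L, 1700001L, 1699500L, 160L, 3455000L),
      c("UNSUPPORTED", "DEL", "DEL", "DEL", "DEL"),
      sprintf("fam9%02d_p", 1:5), rep("proband", 5))
    out <- c(out, showcase)
  }
  out
}

#' Generate toy loops, genes, expression and peak tracks
#'
#' Loops connect gene-proximal left anchors to motif-adjacent right anchors
#' with anchor distances below 900 kb; a `promoter_fraction` of left anchors
#' overlap the (strand-aware, 2 kb upstream) promoter of their gene. CTCF
#' peaks are the planted motifs padded by a flank; histone peak tracks and
#' ASD gene exons are random intervals. Expression is log-normal with a
#' fixed zero fraction.
#'
#' @param spec A [fixture_spec()].
#' @param motifs Motif `GRanges` from [generate_toy_genome()].
#' @return List: `loops` (loop table), `genes` (`GRanges`, named, stranded),
#'   `expression` (data.frame), `ctcf_peaks`, `h3k27ac`, `h3k4me1`,
#'   `h3k27me3`, `asd_genes`, `asd_gene_exons` (`GRanges`).
#' @export
generate_toy_annotations <- function(spec, motifs) {
  set.seed(spec$seed + 2L)
  lo <- FIXTURE_MARGIN_BP
  hi <- spec$chrom_bp - FIXTURE_MARGIN_BP
  chroms <- paste0("chr", seq_len(spec$n_chroms))

  # genes
  n_g <- spec$n_genes * spec$n_chroms
  g_chrom <- rep(chroms, each = spec$n_genes)
  g_tss <- unlist(lapply(seq_len(spec$n_chroms), function(i)
    sort(sample(lo:hi, spec$n_genes))))
  g_strand <- sample(c("+", "-"), n_g, replace = TRUE)
  g_len <- sample(5000:50000, n_g, replace = TRUE)
  g_start <- ifelse(g_strand == "+", g_tss, pmax(1L, g_tss - g_len + 1L))
  g_end <- ifelse(g_strand == "+", g_tss + g_len - 1L, g_tss)
  genes <- GenomicRanges::GRanges(g_chrom,
                                  IRanges::IRanges(g_start, g_end),
                                  strand = g_strand)
  genes$name <- sprintf("GENE%03d", seq_len(n_g))
  names(genes) <- genes$name

  tpm <- round(stats::rlnorm(n_g, meanlog = 2, sdlog = 1.5), 3)
  zero <- sample(n_g, round(spec$tpm_zero_fraction * n_g))
  tpm[zero] <- 0
  expression <- data.frame(gene_id = genes$name, tpm = tpm,
                           stringsAsFactors = FALSE)

  promoters_all <- GenomicRanges::trim(GenomicRanges::promoters(
    gene_tss(genes), upstream = 2000L, downstream = 0L))

  # loops: left anchor at (or deliberately away from) a gene promoter,
  # right anchor snapped to a nearby planted motif
  rows <- list()
  expressed_idx <- which(tpm > 0)
  for (ci in seq_len(spec$n_chroms)) {
    chr <- chroms[ci]
    cand_genes <- intersect(which(g_chrom == chr), expressed_idx)
    chr_motifs <- motifs[as.character(seqnames(motifs)) == chr]
    made <- 0L
    tries <- 0L
    while (made < spec$n_loops && tries < spec$n_loops * 50L) {
      tries <- tries + 1L
      gi <- sample(cand_genes, 1L)
      tss <- g_tss[gi]
      d <- as.integer(stats::runif(1, 100000, 800000))
      target <- tss + d
      if (target > hi) next
      pos2 <- if (length(chr_motifs) > 0L) {
        near <- which.min(abs(start(chr_motifs) - target))
        cand <- start(chr_motifs)[near]
        if (abs(cand - tss) < 850000 && cand - tss > 50000) cand else target
      } else target
      a2 <- c(pos2 - 1000L, pos2 + 1000L)
      at_promoter <- stats::runif(1) < spec$promoter_fraction
      if (at_promoter) {
        # overlap the strand-aware promoter of this gene
        a1 <- if (g_strand[gi] == "+") c(tss - 2500L, tss - 500L)
              else c(tss + 500L, tss + 2500L)
      } else {
        # keep clear of every promoter
        repeat {
          p <- sample(max(lo, tss - 50000L):(tss + 50000L), 1L)
          a1 <- c(p, p + 2000L)
          probe <- GenomicRanges::GRanges(chr,
                                          IRanges::IRanges(a1[1], a1[2]))
          if (length(GenomicRanges::findOverlaps(probe,
                                                 promoters_all)) == 0L)
            break
        }
      }
      if (a1[1] >= a2[1]) next
      if (a2[2] - a1[1] >= 880000L) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom1 = chr, start1 = a1[1], end1 = a1[2],
        chrom2 = chr, start2 = a2[1], end2 = a2[2],
        stringsAsFactors = FALSE)
      made <- made + 1L
    }
  }
  ldf <- do.call(rbind, rows)
  loops <- new_loop_table(ldf$chrom1, ldf$start1, ldf$end1, ldf$chrom2,
                          ldf$start2, ldf$end2)

  random_peaks <- function(n_per_chrom, wmin, wmax) {
    w <- sample(wmin:wmax, n_per_chrom * length(chroms), replace = TRUE)
    s <- unlist(lapply(chroms, function(chr) sort(sample(lo:hi, n_per_chrom))))
    GenomicRanges::GRanges(rep(chroms, each = n_per_chrom),
                           IRanges::IRanges(s, width = w))
  }

  ctcf_peaks <- if (length(motifs) > 0L) {
    GenomicRanges::resize(GenomicRanges::granges(motifs),
                          width = IRanges::width(motifs) + 400L,
                          fix = "center")
  } else GenomicRanges::GRanges()

  # a subset of genes are "ASD genes"; exons are random gene sub-intervals
  asd_idx <- sort(sample(n_g, max(1L, round(0.2 * n_g))))
  asd_genes <- genes[asd_idx]
  exon_rows <- lapply(asd_idx, function(gi) {
    n_ex <- sample(2:5, 1L)
    data.frame(chrom = g_chrom[gi],
               start = sort(sample(g_start[gi]:(g_end[gi] - 400L), n_ex)),
               width = sample(100:400, n_ex, replace = TRUE))
  })
  ed <- do.call(rbind, exon_rows)
  ed <- ed[order(ed$chrom, ed$start), ]
  asd_gene_exons <- GenomicRanges::GRanges(
    ed$chrom, IRanges::IRanges(ed$start, width = ed$width))

  list(loops = loops, genes = genes, expression = expression,
       ctcf_peaks = ctcf_peaks,
       h3k27ac = random_peaks(20L, 500L, 2000L),
       h3k4me1 = random_peaks(20L, 500L, 2000L),
       h3k27me3 = random_peaks(20L, 500L, 2000L),
       asd_genes = asd_genes, asd_gene_exons = asd_gene_exons)
}

#' Generate and write a complete fixture directory
#'
#' Emits FASTA, motif BED, SV TSV + VCF, loops BEDPE, gene/peak/exon BEDs,
#' expression TSV and a manifest JSON into `dir`.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list of file paths.
#' @export
simulate_fixture <- function(spec = fixture_spec(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  toy <- generate_toy_genome(spec)
  variants <- generate_toy_cohort(spec, toy$motifs)
  ann <- generate_toy_annotations(spec, toy$motifs)
  path <- function(f) file.path(dir, f)

  Biostrings::writeXStringSet(toy$genome, path("genome.fa"))
  rtracklayer::export(toy$motifs, path("motifs.bed"), format = "BED")
  write_sv_records(variants, path("variants.tsv"), "tsv")
  write_sv_records(variants, path("variants.vcf"), "vcf")
  write_loops_bedpe(ann$loops, path("loops.bedpe"))
  rtracklayer::export(ann$genes, path("genes.bed"), format = "BED")
  utils::write.table(ann$expression, path("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (key in c("ctcf_peaks", "h3k27ac", "h3k4me1", "h3k27me3",
                "asd_gene_exons", "asd_genes"))
    rtracklayer::export(ann[[key]], path(paste0(key, ".bed")),
                        format = "BED")

  manifest <- list(
    seed = spec$seed,
    files = list(genome = "genome.fa", motifs = "motifs.bed",
                 variants_tsv = "variants.tsv", variants_vcf = "variants.vcf",
                 loops = "loops.bedpe", genes = "genes.bed",
                 expression = "expression.tsv",
                 ctcf_peaks = "ctcf_peaks.bed", h3k27ac = "h3k27ac.bed",
                 h3k4me1 = "h3k4me1.bed", h3k27me3 = "h3k27me3.bed",
                 asd_gene_exons = "asd_gene_exons.bed",
                 asd_genes = "asd_genes.bed"),
    n_variants = length(variants), n_loops = nrow(ann$loops),
    n_motifs = length(toy$motifs))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
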