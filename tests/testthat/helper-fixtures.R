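suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# small geometry used throughout the unit tests: 12 x 64 bp bins,
# 2 bins cropped per side -> 1,024 bp input, 768 bp output
toy_geometry <- function()
  predictor_geometry(input_span_bp = 1024L, bin_bp = 64L, n_bins = 12L,
                     crop_bins_per_side = 2L)

# deterministic random toy chromosome, optionally with planted motifs
toy_genome <- function(len = 5000L, motif_at = integer(0), seed = 42L,
                       motif = surrogate_params()$motif,
                       motif_strand = "+") {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
  strands <- rep_len(motif_strand, length(motif_at))
  for (k in seq_along(motif_at)) {
    planted <- if (strands[k] == "+") motif else
      as.character(reverseComplement(DNAString(motif)))
    substr(s, motif_at[k], motif_at[k] + nchar(motif) - 1L) <- planted
  }
  DNAStringSet(c(chr1 = s))
}

# build a single SV record (1-based closed coordinates)
make_sv <- function(chrom, start, end, svtype, id = "v1",
                    subject = "fam001_p", cohort = "proband",
                    alt_sequence = NA_character_) {
  gr <- GRanges(chrom, IRanges(start, end))
  gr$id <- id
  gr$svtype <- svtype
  gr$subject_id <- subject
  gr$cohort <- cohort
  gr$alt_sequence <- alt_sequence
  gr
}

# hand-build an AlignedMapPair from symmetric matrices (for score oracles)
make_aligned <- function(ref, alt, mask = NULL, diagonal_offset = 1L,
                         geometry = NULL) {
  n <- nrow(ref)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(geometry))
    geometry <- predictor_geometry(input_span_bp = n * 4L + 8L, bin_bp = 4L,
                                   n_bins = n, crop_bins_per_side = 1L)
  structure(list(ref_values = ref, alt_values = alt, joint_mask = mask,
                 variant_bins = integer(0),
                 diagonal_offset = diagonal_offset, geometry = geometry),
            class = "AlignedMapPair")
}

# random symmetric matrix with zero diagonal
random_symmetric <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- stats::rnorm(n * (n - 1) / 2)
  m + t(m)
}

# --- independent oracles -----------------------------------------------------

# average ranks computed by definition (count of smaller values + midrank
# of ties), independent of base rank()
naive_avg_rank <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# Spearman correlation by definition: Pearson on naive average ranks,
# Pearson itself from the sum formula
oracle_spearman <- function(x, y) {
  rx <- naive_avg_rank(x); ry <- naive_avg_rank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), nx)
  mu <- nx * length(y) / 2
  count <- 0L
  for (k in seq_len(ncol(combos))) {
    u <- u_stat(pooled[combos[, k]], pooled[-combos[, k]])
    if (abs(u - mu) >= abs(u_obs - mu) - 1e-9) count <- count + 1L
  }
  count / ncol(combos)
}
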