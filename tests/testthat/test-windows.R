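test_that("prediction windows center on the variant midpoint and shift", {
  geom <- predictor_geometry()
  # variant with 0-based midpoint 2,000,000
  v <- make_sv("chr1", 2000001, 2000001, "DEL")
  w <- build_prediction_window(v, geom, 0L, 3000000L)
  expect_equal(w$start, 1475713L)              # 0-based 1,475,712
  expect_equal(w$end, 2524288L)
  expect_equal(w$end - w$start + 1L, geom$input_span_bp)
  expect_equal(w$clamp_bp, 0L)

  w2 <- build_prediction_window(v, geom, 105000L, 3000000L)
  expect_equal(w2$start, w$start + 105000L)    # additivity
  expect_equal(w2$end, w$end + 105000L)

  # near a contig start the window clamps and records by how much
  v3 <- make_sv("chr1", 100001, 100001, "DEL")
  w3 <- build_prediction_window(v3, geom, 0L, 3000000L)
  expect_equal(w3$start, 1L)
  expect_equal(w3$end, geom$input_span_bp)
  expect_equal(w3$clamp_bp, 424288L)

  expect_error(build_prediction_window(v, geom, 0L, 1000000L),
               class = "svdisrupt_off_contig")
  expect_error(build_prediction_window(v, geom, 600000L, 3000000L),
               "shift_bp")
})

test_that("allele construction follows the per-type substitution rules", {
  geom <- toy_geometry()
  genome <- toy_genome(5000L)
  ref_chr <- as.character(genome[[1]])
  chrom_len <- 5000L

  # inversion: alternate carries the reverse complement, same length
  v <- make_sv("chr1", 2001, 2004, "INV")
  w <- build_prediction_window(v, geom, 0L, chrom_len)
  p <- construct_allele_sequences(w, genome)
  span <- substr(p$ref_seq, p$variant_offset + 1L, p$variant_offset + 4L)
  inv <- substr(p$alt_seq, p$variant_offset + 1L, p$variant_offset + 4L)
  expect_equal(inv, as.character(
    reverseComplement(DNAString(span))))
  expect_equal(p$length_delta, 0L)
  expect_equal(nchar(p$alt_seq), geom$input_span_bp)
  # explicit non-palindromic check of the reverse-complement rule
  expect_equal(svdisrupt:::revcomp_chr("AAAC"), "GTTT")

  # deletion: flanks extended into the chromosome, split evenly
  v <- make_sv("chr1", 2001, 2100, "DEL")     # 100 bp deletion
  w <- build_prediction_window(v, geom, 0L, chrom_len)
  p <- construct_allele_sequences(w, genome)
  expect_equal(nchar(p$alt_seq), geom$input_span_bp)
  expect_equal(p$length_delta, -100L)
  expect_equal(p$pad_left, 50L)
  expect_equal(p$pad_right, 50L)
  # oracle: rebuild the expected alternate from the chromosome string
  w0 <- w$start - 1L
  expected <- paste0(substr(ref_chr, w0 - 50L + 1L, 2000L),
                     substr(ref_chr, 2101L, w$end + 50L))
  expect_equal(p$alt_seq, expected)

  # duplication: an extra copy immediately 5' of the original span
  v <- make_sv("chr1", 2001, 2020, "DUP")
  w <- build_prediction_window(v, geom, 0L, chrom_len)
  p <- construct_allele_sequences(w, genome)
  dup <- substr(ref_chr, 2001L, 2020L)
  at <- p$variant_offset + p$pad_left          # pad_left is negative (trim)
  expect_equal(substr(p$alt_seq, at + 1L, at + 40L), paste0(dup, dup))
  expect_equal(p$length_delta, 20L)
  expect_equal(nchar(p$alt_seq), geom$input_span_bp)

  # complex variant: user-supplied alternate substituted for the span
  v <- make_sv("chr1", 2001, 2010, "CPX", alt_sequence = "TTTT")
  w <- build_prediction_window(v, geom, 0L, chrom_len)
  p <- construct_allele_sequences(w, genome)
  expect_equal(p$length_delta, -6L)
  expect_equal(nchar(p$alt_seq), geom$input_span_bp)
  at <- p$variant_offset + p$pad_left
  expect_equal(substr(p$alt_seq, at + 1L, at + 4L), "TTTT")
})

test_that("flanks outside the variant and padding margins are identical", {
  geom <- toy_geometry()
  genome <- toy_genome(5000L)
  for (svtype in c("DEL", "DUP", "INV")) {
    v <- make_sv("chr1", 2401, 2464, svtype)
    w <- build_prediction_window(v, geom, 0L, 5000L)
    p <- construct_allele_sequences(w, genome)
    expect_equal(nchar(p$ref_seq), geom$input_span_bp, info = svtype)
    expect_equal(nchar(p$alt_seq), geom$input_span_bp, info = svtype)
    vo <- p$variant_offset; pl <- p$pad_left; pr <- p$pad_right
    L <- geom$input_span_bp
    # left flank: identical character for character up to the variant
    if (pl >= 0L) {
      expect_equal(substr(p$alt_seq, pl + 1L, pl + vo),
                   substr(p$ref_seq, 1L, vo), info = svtype)
    } else {
      expect_equal(substr(p$alt_seq, 1L, vo + pl),
                   substr(p$ref_seq, 1L - pl, vo), info = svtype)
    }
    # right flank: identical from the end of the replacement to the window
    ref_right <- substr(p$ref_seq, vo + p$ref_len + 1L, L)
    alt_right_start <- vo + pl + p$alt_len
    if (pr >= 0L) {
      expect_equal(substr(p$alt_seq, alt_right_start + 1L, L - pr),
                   ref_right, info = svtype)
    } else {
      expect_equal(substr(p$alt_seq, alt_right_start + 1L, L),
                   substr(ref_right, 1L, nchar(ref_right) + pr),
                   info = svtype)
    }
  }
})

test_that("the four augmentations are produced and reverse-complement is an involution", {
  geom <- toy_geometry()
  genome <- toy_genome(5000L)
  v <- make_sv("chr1", 2001, 2100, "DEL")
  w <- build_prediction_window(v, geom, 0L, 5000L)
  p <- construct_allele_sequences(w, genome)
  augs <- make_augmentations(p, w, genome)
  expect_length(augs, 4L)
  expect_equal(vapply(augs, function(a) a$augmentation, ""),
               c("identity", "shift_plus1", "shift_minus1", "revcomp"))
  # shifts differ from the identity window by exactly 1 bp at each end
  expect_equal(substr(augs[[2]]$ref_seq, 1L, 100L),
               substr(p$ref_seq, 2L, 101L))
  expect_equal(substr(augs[[3]]$ref_seq, 2L, 101L),
               substr(p$ref_seq, 1L, 100L))
  # reverse complement twice returns the original sequences
  rc <- augs[[4]]
  expect_equal(svdisrupt:::revcomp_chr(rc$ref_seq), p$ref_seq)
  expect_equal(svdisrupt:::revcomp_chr(rc$alt_seq), p$alt_seq)
  # N bases survive reverse complement
  expect_equal(svdisrupt:::revcomp_chr("AACCGGTTNN"), "NNAACCGGTT")
})

test_that("exclusion filters partition variants with first-failing codes", {
  geom <- predictor_geometry()
  genome <- toy_genome(50L)                    # only length checks need it
  sv <- suppressWarnings(c(
    make_sv("chr1", 1, 700001, "DEL", id = "abs"),
    make_sv("chr1", 1, 699500, "DEL", id = "rel"),
    make_sv("chr1", 1, 500, "UNSUPPORTED", id = "ins"),
    make_sv("chr9", 1000, 2000, "DEL", id = "off")))
  res <- apply_exclusion_filters(sv, genome, geom)
  codes <- setNames(res$excluded$code, res$excluded$id)
  expect_equal(codes[["abs"]], "TOO_LONG_ABS")     # > 700 kb
  expect_equal(codes[["rel"]], "TOO_LONG_REL")     # > 2/3 of input span
  expect_equal(codes[["ins"]], "UNKNOWN_ALT")
  expect_equal(codes[["off"]], "OFF_CONTIG")
  expect_equal(length(res$kept) + nrow(res$excluded), length(sv))
})

test_that("N-content filtering uses the 5% reference-window threshold", {
  geom <- toy_geometry()                       # 1,024 bp windows
  base <- toy_genome(5000L)
  s <- as.character(base[[1]])
  # window for the variant below spans ~2038..3061
  s_many <- s; substr(s_many, 2700, 2761) <- strrep("N", 62)   # ~6.1%
  s_few <- s; substr(s_few, 2700, 2739) <- strrep("N", 40)     # ~3.9%
  v <- make_sv("chr1", 2500, 2599, "DEL", id = "v")
  res_many <- apply_exclusion_filters(v, DNAStringSet(c(chr1 = s_many)), geom)
  expect_equal(res_many$excluded$code, "N_CONTENT")
  res_few <- apply_exclusion_filters(v, DNAStringSet(c(chr1 = s_few)), geom)
  expect_equal(length(res_few$kept), 1L)
})

test_that("length conservation holds across types, sizes and shifts", {
  geom <- toy_geometry()
  genome <- toy_genome(6000L, seed = 7L)
  set.seed(11)
  for (k in 1:25) {
    svtype <- sample(c("DEL", "DUP", "INV", "CPX"), 1L)
    len <- sample(1:300, 1L)
    start <- sample(2000:3000, 1L)
    alt <- if (svtype == "CPX")
      paste(sample(c("A", "C", "G", "T"), sample(1:400, 1L), TRUE),
            collapse = "") else NA_character_
    v <- make_sv("chr1", start, start + len - 1L, svtype,
                 alt_sequence = alt)
    w <- build_prediction_window(v, geom, sample(-100:100, 1L), 6000L)
    p <- construct_allele_sequences(w, genome)
    expect_equal(nchar(p$ref_seq), geom$input_span_bp)
    expect_equal(nchar(p$alt_seq), geom$input_span_bp)
    expect_false(grepl("[^ACGTN]", p$alt_seq))
  }
})
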