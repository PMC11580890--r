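test_that("global scores match hand-derived and oracle values", {
  # 3-bin toy: upper-triangle ref (1,2,3) vs alt (3,2,1) -> rho = -1
  ref <- matrix(0, 3, 3); ref[upper.tri(ref)] <- c(1, 2, 3)
  ref <- ref + t(ref)
  alt <- matrix(0, 3, 3); alt[upper.tri(alt)] <- c(3, 2, 1)
  alt <- alt + t(alt)
  aligned <- make_aligned(ref, alt)
  sc <- score_global(aligned)
  expect_equal(sc$spearman_score, 2)
  expect_equal(sc$mse_score, (4 + 0 + 4) / 3)

  # identical maps score exactly zero
  sc0 <- score_global(make_aligned(ref, ref))
  expect_equal(sc0$spearman_score, 0)
  expect_equal(sc0$mse_score, 0)

  # monotone transformation leaves the rank score at zero, MSE positive
  scm <- score_global(make_aligned(ref, 2 * ref + 1))
  expect_equal(scm$spearman_score, 0)
  expect_gt(scm$mse_score, 0)

  # constant maps have undefined correlation, reported as missing
  scc <- score_global(make_aligned(matrix(1, 3, 3), ref))
  expect_true(is.na(scc$spearman_score))
  expect_match(scc$reason, "constant")
})

test_that("Spearman scoring agrees with a brute-force rank oracle", {
  set.seed(101)
  for (k in 1:100) {
    n <- sample(5:12, 1L)
    ref <- random_symmetric(n)
    alt <- random_symmetric(n)
    if (stats::runif(1) < 0.5) {
      # inject ties to exercise average ranks
      ref[upper.tri(ref)] <- round(ref[upper.tri(ref)], 1)
      ref <- ref * 0; ref[upper.tri(ref)] <- round(stats::rnorm(n * (n - 1) / 2), 1)
      ref <- ref + t(ref)
    }
    mask <- stats::runif(n) > 0.2
    if (sum(mask) < 4) mask[] <- TRUE
    aligned <- make_aligned(ref, alt, mask = mask)
    sc <- score_global(aligned)
    ok <- outer(mask, mask, "&") & abs(outer(1:n, 1:n, "-")) >= 1 &
      upper.tri(ref)
    x <- ref[ok]; y <- alt[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(sc$spearman_score, 1 - oracle_spearman(x, y),
                 tolerance = 1e-12)
    expect_equal(sc$mse_score, mean((x - y)^2), tolerance = 1e-12)
  }
})

test_that("alignment pads, masks and guards around the variant", {
  geom <- toy_geometry()
  genome <- toy_genome(5000L)
  predict_both <- function(v) {
    w <- build_prediction_window(v, geom, 0L, 5000L)
    p <- construct_allele_sequences(w, genome)
    ref <- predict_contact_map(p$ref_seq, geom)
    alt <- predict_contact_map(p$alt_seq, geom)
    align_allele_maps(ref, alt, p, geom)
  }
  # an inversion needs no padding; only variant + guard bins are masked
  # variant spans exactly output bins 6-7 of its (clamp-free) window
  v <- make_sv("chr1", 2001, 2128, "INV")
  a <- predict_both(v)
  expect_equal(which(!a$joint_mask), 5:8)      # one guard bin each side

  # a 2-bin deletion shifts flanking bins by one bin on each side
  v <- make_sv("chr1", 2001, 2128, "DEL")
  a <- predict_both(v)
  expect_true(all(a$variant_bins %in% which(!a$joint_mask)))
  p <- surrogate_params()
  f <- function(d) -p$alpha * log(d + 1)
  # bins on one side of the deletion compare the same sequence at the same
  # separation: identical values
  expect_equal(a$alt_values[2, 4], a$ref_values[2, 4])
  expect_equal(a$alt_values[10, 12], a$ref_values[10, 12])
  # bins straddling the deletion are two bins closer in the alternate
  # allele (the deleted material is gone), so contact strengthens
  expect_equal(a$ref_values[3, 10], f(7))
  expect_equal(a$alt_values[3, 10], f(5))

  # identity null for every type: alt identical to ref scores zero
  for (svtype in c("DEL", "DUP", "INV", "CPX")) {
    alt <- if (svtype == "CPX") strrep("A", 10) else NA_character_
    v <- make_sv("chr1", 2401, 2410, svtype, alt_sequence = alt)
    w <- build_prediction_window(v, geom, 0L, 5000L)
    p <- construct_allele_sequences(w, genome)
    ref <- predict_contact_map(p$ref_seq, geom)
    p_id <- p; p_id$alt_seq <- p$ref_seq
    p_id$alt_len <- p_id$ref_len; p_id$length_delta <- 0L
    p_id$pad_left <- 0L; p_id$pad_right <- 0L
    a <- align_allele_maps(ref, ref, p_id, geom)
    sc <- score_global(a)
    expect_equal(sc$spearman_score, 0, info = svtype)
    expect_equal(sc$mse_score, 0, info = svtype)
  }

  # masking everything is an error, not a silent zero
  v <- make_sv("chr1", 2101, 2700, "INV")      # covers every output bin
  expect_error(predict_both(v), "nothing left to compare")
})

test_that("disruption tracks localize per-bin differences", {
  n <- 8
  ref <- random_symmetric(n)
  alt <- ref
  alt[4, ] <- alt[4, ] + 1; alt[, 4] <- t(alt[4, ]); alt[4, 4] <- ref[4, 4]
  aligned <- make_aligned(ref, alt)
  tr <- disruption_track(aligned, "mse")
  expect_equal(which.max(tr$values), 4L)
  # other bins each see exactly one differing partner entry
  expect_true(all(tr$values[-4] < tr$values[4]))

  # identical maps give an all-zero track on unmasked bins
  tr0 <- disruption_track(make_aligned(ref, ref), "mse")
  expect_true(all(tr0$values == 0))

  # default geometry yields 448 values
  g <- predictor_geometry()
  big <- matrix(0, g$n_bins, g$n_bins)
  tr448 <- disruption_track(make_aligned(big, big, diagonal_offset = 2L,
                                         geometry = g), "mse")
  expect_length(tr448$values, 448L)
})

test_that("weight tracks apply the 1-bp overlap rule", {
  geom <- toy_geometry()
  v <- make_sv("chr1", 2000, 2000, "DEL")
  w <- build_prediction_window(v, geom, 0L, 5000L)
  # output bins are 64 bp starting at window$start - 1 + 128
  out0 <- w$start - 1L + 128L
  empty <- build_weight_track(GRanges(), w, geom, 10)
  expect_equal(empty$values, rep(1, 12))

  one_bin <- GRanges("chr1", IRanges(out0 + 3L * 64L + 1L, out0 + 4L * 64L))
  wt <- build_weight_track(one_bin, w, geom, 10)
  expect_equal(which(wt$values == 10), 4L)
  expect_equal(sum(wt$values == 1), 11L)

  # straddling a bin boundary by 1 bp on each side hits both bins
  straddle <- GRanges("chr1", IRanges(out0 + 4L * 64L, out0 + 4L * 64L + 1L))
  wt2 <- build_weight_track(straddle, w, geom, 10)
  expect_equal(which(wt2$values == 10), c(4L, 5L))
})

test_that("weighted scores normalize, localize to ROIs, and degrade to unweighted", {
  g <- predictor_geometry()
  d <- rep(0, g$n_bins); d[100:101] <- 0.4
  track <- structure(list(values = d, metric = "mse",
                          mask = rep(TRUE, g$n_bins)),
                     class = "DisruptionTrack")
  wts <- structure(list(values = ifelse(seq_len(g$n_bins) %in% 100:101,
                                        10, 1), scale = 10),
                   class = "WeightTrack")
  expect_equal(weighted_score(track, wts, "weighted"), 8 / 466,
               tolerance = 1e-12)
  expect_equal(weighted_score(track, mode = "unweighted"), 0.8 / 448,
               tolerance = 1e-12)
  expect_equal(weighted_score(track, wts, "roi_only"), 0.4)
  # the unnormalized (literal) form is available behind the flag
  expect_equal(weighted_score(track, wts, "weighted", normalize = FALSE),
               8 / 448, tolerance = 1e-12)

  # uniform disruption: weighted equals unweighted exactly
  tu <- track; tu$values <- rep(0.1, g$n_bins)
  expect_equal(weighted_score(tu, wts, "weighted"), 0.1)

  # scale 1 and full-ROI weights reduce to the unweighted score
  set.seed(3)
  tr <- track; tr$values <- stats::runif(g$n_bins)
  w1 <- wts; w1$values <- rep(1, g$n_bins)
  expect_equal(weighted_score(tr, w1, "weighted"),
               weighted_score(tr, mode = "unweighted"))
  wall <- wts; wall$values <- rep(10, g$n_bins)
  expect_equal(weighted_score(tr, wall, "weighted"),
               weighted_score(tr, mode = "unweighted"))

  # raising disruption at ROI bins raises weighted relative to unweighted
  tr2 <- tr; tr2$values[100:101] <- tr2$values[100:101] + 1
  rel <- function(t) weighted_score(t, wts, "weighted") -
    weighted_score(t, mode = "unweighted")
  expect_gt(rel(tr2), rel(tr))
  tr3 <- tr; tr3$values[100:101] <- 0
  expect_lt(rel(tr3), rel(tr))
})

test_that("masking additional bins never changes scores from remaining bins", {
  set.seed(17)
  n <- 10
  ref <- random_symmetric(n); alt <- random_symmetric(n)
  mask1 <- rep(TRUE, n)
  a1 <- make_aligned(ref, alt, mask = mask1)
  mask2 <- mask1; mask2[c(2, 7)] <- FALSE
  a2 <- make_aligned(ref, alt, mask = mask2)
  ok2 <- outer(mask2, mask2, "&") & abs(outer(1:n, 1:n, "-")) >= 1 &
    upper.tri(ref)
  # recompute scores from the surviving entries of the unmasked pair
  expect_equal(score_global(a2)$mse_score,
               mean((ref[ok2] - alt[ok2])^2))
  expect_equal(score_global(a2)$spearman_score,
               1 - oracle_spearman(ref[ok2], alt[ok2]))
})

test_that("augmentation averaging is the arithmetic mean with honest tags", {
  rows <- data.frame(variant_id = "v", spearman_score = c(0.1, 0.2, 0.3, 0.4),
                     mse_score = c(1, 2, 3, 4) / 10,
                     augmentation = c("identity", "shift_plus1",
                                      "shift_minus1", "revcomp"),
                     stringsAsFactors = FALSE)
  avg <- average_augmented(rows)
  expect_equal(avg$spearman_score, 0.25)
  expect_equal(avg$augmentation, "averaged-of-4")
  avg3 <- average_augmented(rows[1:3, ])
  expect_equal(avg3$augmentation, "averaged-of-3")
  expect_equal(avg3$spearman_score, 0.2)

  same <- rows; same$spearman_score <- 0.2
  expect_equal(average_augmented(same)$spearman_score, 0.2)
})

test_that("augmented variant scoring is reverse-complement consistent", {
  geom <- toy_geometry()
  genome <- toy_genome(5000L, motif_at = 2300L)
  v <- make_sv("chr1", 2501, 2600, "DEL")
  plain <- score_variant(v, genome, geom, augment = FALSE)
  aug <- score_variant(v, genome, geom, augment = TRUE)
  expect_equal(aug$n_augment, 4L)
  # the surrogate is exactly RC-equivariant, and 1 bp shifts rarely move a
  # bin boundary, so the averaged score sits near the unaugmented one
  expect_equal(aug$spearman_score, plain$spearman_score, tolerance = 0.05)
})

test_that("tiled 1-bp deletions recover a planted motif and stay silent elsewhere", {
  geom <- toy_geometry()
  genome <- toy_genome(6000L, motif_at = 3000L, seed = 9L)
  region <- GRanges("chr1", IRanges(2970, 3050))
  prof <- tiled_deletion_scan(region, genome, geom)
  expect_equal(nrow(prof), 81L)
  peak <- prof$pos[which.max(prof$score)]
  expect_gte(peak, 3000L)                      # inside the 19-mer
  expect_lte(peak, 3018L)
  # deleting inside the motif (destroying the boundary) dominates any
  # off-motif score (at most a sub-bin boundary jitter)
  inside <- prof$score[prof$pos >= 3000 & prof$pos <= 3018]
  outside <- prof$score[prof$pos < 3000 | prof$pos > 3018]
  expect_gt(max(inside), max(outside))

  # in a window with no motif at all the profile is numerically zero
  far <- GRanges("chr1", IRanges(1000, 1040))
  prof0 <- tiled_deletion_scan(far, genome, geom)
  expect_true(all(prof0$score < 1e-9))

  expect_error(tiled_deletion_scan(GRanges("chr1", IRanges(1, 50000)),
                                   genome, geom), "scan cap")
})
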