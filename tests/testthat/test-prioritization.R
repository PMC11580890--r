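test_that("percentile thresholds use linear interpolation", {
  expect_equal(compute_percentile_thresholds(c(0, 1, 2, 3, 4), 50), 2)
  expect_equal(compute_percentile_thresholds(c(1, 2, 3, 4), 85), 3.55)
  expect_equal(compute_percentile_thresholds(rep(7, 5), 30), 7)
  expect_equal(compute_percentile_thresholds(rep(7, 5), 95), 7)
  expect_error(compute_percentile_thresholds(numeric(0), 50), "no finite")
})

test_that("prediction quality is the masked upper-triangle MSE", {
  g <- toy_geometry()
  vals <- random_symmetric(12)
  pred <- contact_map(vals, g, diagonal_offset = 1L)
  expect_equal(prediction_quality(pred, vals), 0)
  expect_equal(prediction_quality(pred, vals + 0.5), 0.25)

  # brute-force oracle on random matrices with masked bins
  set.seed(41)
  for (k in 1:20) {
    a <- random_symmetric(12)
    b <- random_symmetric(12)
    mask <- stats::runif(12) > 0.2
    pm <- contact_map(a, g, mask = mask, diagonal_offset = 1L)
    acc <- 0; cnt <- 0L
    for (i in 1:11) for (j in (i + 1):12) {
      if (mask[i] && mask[j] && abs(i - j) >= 1) {
        acc <- acc + (a[i, j] - b[i, j])^2; cnt <- cnt + 1L
      }
    }
    expect_equal(prediction_quality(pm, b), acc / cnt, tolerance = 1e-12)
  }
})

test_that("experimental matrices re-bin onto prediction bins", {
  g <- toy_geometry()
  genome <- toy_genome(5000L)
  v <- make_sv("chr1", 2500, 2500, "DEL")
  w <- build_prediction_window(v, g, 0L, 5000L)
  s <- svdisrupt:::get_sequence(genome, "chr1", w$start, w$end)
  pred <- predict_contact_map(s, g)
  # a finer experimental matrix (32 bp bins) covering the output region
  out_lo0 <- w$start - 1L + 128L
  n_exp <- 24L
  exp_vals <- matrix(0, n_exp, n_exp)
  for (i in seq_len(n_exp)) for (j in seq_len(n_exp))
    exp_vals[i, j] <- pred$values[ceiling(i / 2), ceiling(j / 2)]
  exp_vals[is.na(exp_vals)] <- NA
  mat <- structure(list(region = GRanges("chr1",
                                         IRanges(out_lo0 + 1L,
                                                 out_lo0 + n_exp * 32L)),
                        bin_bp = 32L, values = exp_vals,
                        mask = rep(TRUE, n_exp)),
                   class = "DenseContactMatrix")
  # the block means reproduce the prediction exactly -> MSE 0
  expect_equal(prediction_quality(pred, mat, w), 0)
})

test_that("sibling similarity needs reciprocal overlap above half", {
  # proband 0-based 1,000-2,000; sibling 1,400-2,400: overlap 600 on both
  pro <- make_sv("chr1", 1001, 2000, "DEL")
  sib1 <- make_sv("chr1", 1401, 2400, "DEL", cohort = "sibling")
  expect_true(sibling_similarity(pro, sib1))
  # disjoint variants are never similar
  sib2 <- make_sv("chr1", 9001, 9500, "DEL", cohort = "sibling")
  expect_false(sibling_similarity(pro, sib2))
  # overlap 1,000 exceeds half the proband but not half the sibling
  sib3 <- make_sv("chr1", 1001, 10000, "DEL", cohort = "sibling")
  expect_false(sibling_similarity(pro, sib3))
  expect_false(sibling_similarity(pro, sib2[0]))
})

criteria_context <- function(variant) {
  # a context engineered so `variant` passes all 12 criteria
  list(
    scores = list(global = 0.5, weighted = 0.4, unweighted = 0.2,
                  roi_only = 0.6, prediction_mse = 0.01),
    all_global_scores = seq(0, 0.45, length.out = 20),
    all_prediction_mse = seq(0.005, 0.2, length.out = 20),
    asd_gene_exons = GRanges("chr1", IRanges(700000, 700500)),
    asd_genes = GRanges("chr1", IRanges(690000, 710000)),
    subject_variants = variant,
    sibling_svs = GRanges("chr1", IRanges(5e6, 5.1e6)),
    expressed_exons = GRanges("chr1", IRanges(800000, 800500)),
    re_peaks = GRanges("chr1", IRanges(900000, 900500)),
    ctcf_peaks = GRanges("chr1", IRanges(999000, 1001000)))
}

test_that("a variant built to satisfy all criteria passes all twelve", {
  v <- make_sv("chr1", 1000001, 1001000, "DEL", id = "good")
  res <- evaluate_criteria(v, criteria_context(v))
  expect_equal(nrow(res), 12L)
  expect_true(all(res$passed))
  expect_equal(sum(res$required), 7L)
})

test_that("criteria flip independently with their inputs", {
  v <- make_sv("chr1", 1000001, 1001000, "DEL", id = "v")
  ctx <- criteria_context(v)

  # 600 kb from the nearest ASD gene: only the distance criterion fails
  ctx_far <- ctx
  ctx_far$asd_genes <- GRanges("chr1", IRanges(1601001, 1620000))
  ctx_far$asd_gene_exons <- GRanges("chr1", IRanges(1601001, 1601500))
  res <- evaluate_criteria(v, ctx_far)
  expect_false(res$passed[res$criterion == "near_asd_gene"])
  expect_true(all(res$passed[res$criterion != "near_asd_gene"]))

  # a non-deletion fails only the deletion criterion
  v_inv <- make_sv("chr1", 1000001, 1001000, "INV", id = "v")
  res <- evaluate_criteria(v_inv, criteria_context(v_inv))
  expect_false(res$passed[res$criterion == "deletion"])
  expect_true(all(res$passed[res$criterion != "deletion"]))

  # swallowing a whole CTCF peak fails the clipping criterion
  ctx_sw <- ctx
  ctx_sw$ctcf_peaks <- GRanges("chr1", IRanges(1000100, 1000200))
  res <- evaluate_criteria(v, ctx_sw)
  expect_false(res$passed[res$criterion == "on_ctcf"])

  # missing annotation makes the criterion unevaluable, not passed
  ctx_na <- ctx; ctx_na$ctcf_peaks <- NULL
  res <- evaluate_criteria(v, ctx_na)
  expect_true(is.na(res$passed[res$criterion == "on_ctcf"]))
  expect_false(any(is.na(res$passed[res$criterion != "on_ctcf"])))
})

test_that("required passes shrink as thresholds tighten", {
  v <- make_sv("chr1", 1000001, 1001000, "DEL", id = "v")
  ctx <- criteria_context(v)
  n_req <- function(cfg) {
    r <- evaluate_criteria(v, ctx, cfg)
    sum(r$passed[r$required], na.rm = TRUE)
  }
  loose <- n_req(criteria_config(score_pctl = 50, mse_pctl = 95))
  tight <- n_req(criteria_config(score_pctl = 99, mse_pctl = 5))
  expect_lte(tight, loose)
})

test_that("2x2 enrichment matches the closed form and chisq.test", {
  # worked example: [[20,80],[10,190]]
  res <- svdisrupt:::chisq_2x2(matrix(c(20, 80, 10, 190), 2, byrow = TRUE))
  expect_equal(res$chi2, 300 * (20 * 190 - 80 * 10)^2 /
                 (100 * 200 * 30 * 270))
  expect_equal(res$chi2, 16.66667, tolerance = 1e-5)
  expect_equal(res$odds_ratio, (20 * 190) / (80 * 10))

  set.seed(51)
  for (k in 1:100) {
    tab <- matrix(rpois(4, 20) + 1L, 2)
    ours <- svdisrupt:::chisq_2x2(tab)
    ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }

  zero <- svdisrupt:::chisq_2x2(matrix(c(0, 0, 5, 7), 2, byrow = TRUE))
  expect_true(is.na(zero$chi2))
})

test_that("genome-binned enrichment counts bins and flags overlap", {
  sizes <- c(chr1 = 2500000L)                  # 3 bins (last partial kept)
  variants <- make_sv("chr1", 100, 200, "DEL")
  creints <- new_loop_table("chr1", 150L, 250L, "chr1", 1200000L, 1200100L)
  creints$promoter_genes <- "G"
  res <- enrichment_chisq_1mb(variants, creints, sizes)
  expect_equal(sum(res$contingency), 3L)
  expect_equal(res$contingency[1, 1], 1L)      # bin 1: SV + CREint anchor
  expect_equal(res$contingency[2, 1], 1L)      # bin 2: CREint anchor only
  expect_equal(res$contingency[2, 2], 1L)
})

test_that("length-quantile cohort tests reproduce exact rank-sum results", {
  # cutoffs at 2.75 / 4.5 / 6.25 for pooled lengths 1..8
  df <- data.frame(cohort = rep(c("proband", "sibling"), 8),
                   length = rep(1:8, each = 2),
                   score = stats::runif(16))
  res <- cohort_length_quantile_test(df)
  expect_equal(res$cutoffs, c(2.75, 4.5, 6.25))
  expect_equal(as.integer(table(findInterval(df$length, res$cutoffs,
                                             left.open = TRUE))),
               rep(4L, 4))

  # complete separation at n = 5 vs 5: U = 25, exact p = 2/252
  df2 <- data.frame(cohort = rep(c("proband", "sibling"), each = 5),
                    length = rep(10, 10),
                    score = c(6:10, 1:5))
  res2 <- cohort_length_quantile_test(df2, n_quantiles = 1L)
  expect_equal(res2$tests$U, 25)
  expect_equal(res2$tests$p, 2 / 252, tolerance = 1e-12)

  # small strata are skipped with a reason, never tested silently
  df3 <- data.frame(cohort = c("proband", "sibling", "sibling"),
                    length = c(1, 2, 3), score = c(1, 2, 3))
  res3 <- cohort_length_quantile_test(df3, n_quantiles = 1L)
  expect_false(is.na(res3$tests$skipped))
})

test_that("normal-approximation rank-sum p agrees with exact permutation", {
  set.seed(61)
  for (k in 1:20) {
    x <- stats::rnorm(8); y <- stats::rnorm(8, mean = stats::runif(1, 0, 1))
    approx_p <- suppressWarnings(stats::wilcox.test(
      x, y, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(approx_p - oracle_mw_exact_p(x, y)), 0.02)
  }
})
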