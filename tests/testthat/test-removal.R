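# Most tests run at a reduced scale (16 channels, fs 512) to keep the suite
# fast; the full benchmark conditions are exercised in test-acceptance.R.

m16 <- hemi_montage(16)
plan16 <- quiet(build_subspace_plan(m16, 8))
cfg16 <- removal_config(L = 8)

test_that("clean low-frequency records pass through almost unchanged (D ~ I)", {
  # full-rank mixture of pink 1-45 Hz sources: every separated component is
  # low-frequency dominated, so nothing is classified as artifact
  set.seed(101)
  S <- t(replicate(16, subica:::band_noise(512, 512, 1, 45, slope = 1)))
  clean <- matrix(rnorm(256), 16) %*% S
  res <- quiet(remove_artifacts_segment(clean, 512, plan16, cfg16, seed = 1))
  expect_equal(sum(res$removed_counts), 0)
  expect_lt(max(abs(res$D - diag(16))), 1e-6)
  expect_gt(mean_correlation(res$cleaned, clean), 0.999)
  expect_equal(res$effective_rank, 16L)
})

test_that("artifact removal improves correlation with the clean truth", {
  gt <- simulate_trial(m16, xi = 4, duration_s = 1, fs = 512, seed = 102)
  res <- quiet(remove_artifacts_segment(gt$mixed$data, 512, plan16, cfg16, seed = 2))
  r_before <- mean_correlation(gt$mixed$data, gt$clean$data)
  r_after <- mean_correlation(res$cleaned, gt$clean$data)
  expect_gt(r_after, r_before)
  expect_gt(sum(res$removed_counts), 0)
})

test_that("forcing every component to be removed zeroes the output exactly", {
  set.seed(103)
  x <- matrix(rnorm(16 * 600), 16)
  cfg0 <- removal_config(L = 8, classifier = function(S, fs, bands)
    list(keep = rep(FALSE, nrow(S)), alpha = rep(0, nrow(S))))
  res <- quiet(remove_artifacts_segment(x, 512, plan16, cfg0, seed = 3))
  expect_equal(max(abs(res$cleaned)), 0)
  expect_equal(max(abs(res$D)), 0)
  expect_equal(res$removed_counts, rep(8L, 16))
})

test_that("with frozen masks the removal is the linear operator D", {
  gt <- simulate_trial(m16, xi = 1, duration_s = 1, fs = 512, seed = 104)
  x <- gt$mixed$data
  r1 <- quiet(remove_artifacts_segment(x, 512, plan16, cfg16, seed = 4))
  # the materialized operator reproduces the factored computation ...
  expect_equal(r1$D %*% x, r1$cleaned, tolerance = 1e-9)
  # ... and, masks frozen inside D, commutes with any linear combination
  set.seed(104)
  y <- matrix(rnorm(length(x)), nrow(x))
  expect_equal(r1$D %*% (2.5 * x - 3 * y),
               2.5 * r1$cleaned - 3 * (r1$D %*% y), tolerance = 1e-9)
})

test_that("operator rank stays between M - removed and M", {
  gt <- simulate_trial(m16, xi = 4, duration_s = 1, fs = 512, seed = 105)
  res <- quiet(remove_artifacts_segment(gt$mixed$data, 512, plan16, cfg16, seed = 5))
  sv <- svd(res$D)$d
  num_rank <- sum(sv > 1e-10 * sv[1])
  expect_lte(num_rank, 16)
  expect_gte(num_rank, 16 - sum(res$removed_counts))
  expect_lte(res$effective_rank, 16)
})

test_that("effective rank count matches a brute-force cumulative scan", {
  expect_equal(operator_rank_count(diag(10)), 10L)
  D1 <- diag(c(1, rep(0, 9)))
  expect_equal(operator_rank_count(D1), 1L)
  set.seed(106)
  for (i in 1:5) {
    D <- matrix(rnorm(64), 8)
    sv <- sort(svd(D)$d^2, decreasing = TRUE)
    oracle <- which(cumsum(sv) / sum(sv) >= 0.99)[1]
    expect_equal(operator_rank_count(D), as.integer(oracle))
  }
  # "absolute" energy variant
  D <- diag(c(4, 1, 1))
  expect_equal(operator_rank_count(D, 0.5, energy = "absolute"), 1L)
  expect_equal(operator_rank_count(D, 0.9, energy = "absolute"), 3L)
})

test_that("records are processed segment-wise with exact lengths and determinism", {
  rec <- simulate_clean_eeg(m16, duration_s = 3, fs = 512, seed = 107)
  res1 <- quiet(process_record(rec, m16, removal_config(L = 8, seg_len_s = 1, seed = 9)))
  expect_equal(dim(res1$cleaned$data), dim(rec$data))
  expect_length(res1$segments, 3)
  res2 <- quiet(process_record(rec, m16, removal_config(L = 8, seg_len_s = 1, seed = 9)))
  expect_identical(res1$cleaned$data, res2$cleaned$data)
  # clean input: per-segment energy preserved within 1%
  for (si in 1:3) {
    idx <- ((si - 1) * 512 + 1):(si * 512)
    e_in <- sum(rec$data[, idx]^2)
    e_out <- sum(res1$cleaned$data[, idx]^2)
    expect_lt(abs(e_out - e_in) / e_in, 0.01)
  }
})

test_that("short trailing segments are passed through with a warning", {
  rec <- simulate_clean_eeg(m16, duration_s = 1.3, fs = 512, seed = 108)
  w <- capture_warnings(
    res <- process_record(rec, m16, removal_config(L = 8, seg_len_s = 1, seed = 9)))
  expect_true(any(grepl("partial segment", w)))
  expect_length(res$segments, 1)
  tail_idx <- 513:ncol(rec$data)
  expect_equal(res$cleaned$data[, tail_idx], rec$data[, tail_idx])
})

test_that("a second pass over cleaned data changes it only mildly", {
  gt <- simulate_trial(m16, xi = 1, duration_s = 1, fs = 512, seed = 109)
  p1 <- quiet(remove_artifacts_segment(gt$mixed$data, 512, plan16, cfg16, seed = 6))
  p2 <- quiet(remove_artifacts_segment(p1$cleaned, 512, plan16, cfg16, seed = 7))
  rel_change <- sum((p2$cleaned - p1$cleaned)^2) / sum(p1$cleaned^2)
  expect_lt(rel_change, 0.2)   # soft idempotence-tendency, loose bound
})

test_that("degenerate inputs are handled explicitly", {
  expect_error(quiet(remove_artifacts_segment(matrix(rnorm(10 * 100), 10), 512,
                                              plan16, cfg16)), "plan expects 16")
  expect_warning(res <- remove_artifacts_segment(matrix(0, 16, 400), 512,
                                                 plan16, cfg16),
                 "identically zero")
  expect_equal(res$cleaned, matrix(0, 16, 400))
})
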