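m9 <- patch_montage(9)

test_that("plain ICA (method A) cleans a well-separated low-dimensional mixture", {
  gt <- simulate_trial(m9, xi = 1, duration_s = 2, seed = 201)
  res <- quiet(method_plain_ica(gt$mixed$data, 1024, removal_config(), seed = 1))
  expect_gt(mean_correlation(res$cleaned, gt$clean$data),
            mean_correlation(gt$mixed$data, gt$clean$data))
  expect_gt(res$n_removed, 0)
})

# Full-rank mixture of pink 1-45 Hz sources: every component classifies as
# brain signal, so cleaning must be the identity.
pink_full_rank <- function(M, N, fs, seed) {
  set.seed(seed)
  S <- t(replicate(M, subica:::band_noise(N, fs, 1, 45, slope = 1)))
  matrix(rnorm(M * M), M) %*% S
}

test_that("plain ICA leaves artifact-free data intact", {
  clean <- pink_full_rank(9, 1024, 1024, seed = 202)
  res <- quiet(method_plain_ica(clean, 1024, removal_config(), seed = 2))
  expect_equal(res$n_removed, 0)
  expect_lt(max(abs(res$cleaned - clean)) / max(abs(clean)), 1e-6)
})

test_that("plain ICA completes on the overlearning-prone scale (smoke)", {
  m64 <- hemi_montage(64)
  gt <- simulate_trial(m64, xi = 1, seed = 203)
  res <- quiet(method_plain_ica(gt$mixed$data, 1024, removal_config(), seed = 3))
  expect_equal(dim(res$cleaned), dim(gt$mixed$data))
  expect_true(all(is.finite(res$cleaned)))
})

test_that("the 1 Hz high-pass of method Ba behaves as designed", {
  fs <- 1024
  hp <- signal::butter(4, 1 / (fs / 2), type = "high")
  t4 <- (0:(4 * fs - 1)) / fs
  slow <- sin(2 * pi * 0.3 * t4)
  atten_db <- 10 * log10(mean(zerophase_filter(hp, slow)[fs:(3 * fs)]^2) / 0.5)
  expect_lt(atten_db, -20)
  dc <- rep(1.5, 4 * fs)
  expect_lt(max(abs(zerophase_filter(hp, dc))), 0.02)
  # on clean high-passed data the method reduces to near method A behavior
  clean <- pink_full_rank(9, 1024, fs, seed = 204)
  res <- quiet(method_highpass_fixed(clean, fs, removal_config(), seed = 4))
  expect_equal(res$n_removed, 0)
  expect_lt(max(abs(res$cleaned - clean)) / max(abs(clean)), 1e-6)
})

test_that("AR-based high-pass (method Bb) whitens low-frequency content and is deterministic", {
  set.seed(205)
  fs <- 1024
  # strong AR(1) low-frequency process: whitening must cut low-band power
  n <- 4096
  x1 <- as.numeric(stats::filter(rnorm(n), 0.98, method = "recursive"))
  x <- rbind(x1, x1 + 0.1 * rnorm(n))
  coefs <- vapply(1:2, function(i)
    as.numeric(stats::ar(x[i, ], aic = FALSE, order.max = 8,
                         method = "ols")$ar), numeric(8))
  abar <- rowMeans(coefs)
  e <- as.numeric(signal::filter(c(1, -abar), 1, x1))
  # low-frequency (<= 5 Hz) power via Welch PSD, normalized per unit variance
  lo_pow <- function(s) {
    w <- welch_psd(s / sd(s), fs)
    mean(w$psd[w$freq >= 1 & w$freq <= 5])
  }
  expect_lt(10 * log10(lo_pow(e) * var(e) / (lo_pow(x1) * var(x1))), -10)
  gt <- simulate_trial(m9, xi = 1, seed = 206)
  r1 <- quiet(method_highpass_ar(gt$mixed$data, fs, removal_config(), seed = 6))
  r2 <- quiet(method_highpass_ar(gt$mixed$data, fs, removal_config(), seed = 6))
  expect_identical(r1$cleaned, r2$cleaned)
})

test_that("PCA reduction (method C) caps the output rank and spans the top PCs", {
  clean <- simulate_clean_eeg(hemi_montage(16), fs = 512, seed = 207)
  res <- quiet(method_pca_reduce(clean$data, 512, n_pcs = 12,
                                 removal_config(), seed = 7))
  sv <- svd(res$cleaned - rowMeans(res$cleaned))$d
  expect_lte(sum(sv > 1e-8 * sv[1]), 12)
  # output (centered) lies in the span of the top PCs
  p <- subica:::top_pcs(clean$data, 12)
  resid <- (diag(16) - tcrossprod(p$U)) %*% (res$cleaned - rowMeans(res$cleaned))
  expect_lt(max(abs(resid)) / max(abs(res$cleaned)), 1e-8)
})

test_that("PCA reduction with all PCs and no artifacts is lossless", {
  clean <- simulate_clean_eeg(m9, seed = 208)
  res <- quiet(method_pca_reduce(clean$data, 1024, n_pcs = 9,
                                 removal_config(), seed = 8))
  expect_lt(max(abs(res$cleaned - clean$data)) / max(abs(clean$data)), 1e-6)
})

test_that("PCA+regression (method D) leaves residuals orthogonal to its components", {
  gt <- simulate_trial(m9, xi = 4, seed = 209)
  x <- gt$mixed$data
  sep <- separate_subspace(crossprod(subica:::top_pcs(x, 3)$U,
                                     x - rowMeans(x)), seed = 9)
  res <- quiet(method_pca_regression(x, 1024, n_pcs = 3, removal_config(), seed = 9))
  S <- sep$S - rowMeans(sep$S)
  cors <- abs(stats::cor(t(res$cleaned), t(S)))
  expect_lt(max(cors), 1e-8)
})

test_that("method D removes an artifact spanned by the strongest components but harms clean data", {
  set.seed(210)
  mh <- hemi_montage(9)
  clean <- simulate_clean_eeg(mh, seed = 211)
  # strong artifact confined to a 2-dimensional spatial subspace with spread
  # topographies: it must dominate the top PCs and be subtracted away
  g1 <- rnorm(9); g2 <- rnorm(9)
  art <- 20 * (g1 %o% rnorm(1024) + g2 %o% rnorm(1024))
  x <- clean$data + art
  res <- quiet(method_pca_regression(x, 1024, n_pcs = 3, removal_config(), seed = 10))
  resid_art <- vapply(1:9, function(ch)
    abs(uncentered_r(res$cleaned[ch, ], art[ch, ])), numeric(1))
  expect_lt(max(resid_art), 0.1)
  expect_gt(mean_correlation(res$cleaned, clean$data),
            mean_correlation(x, clean$data))
  # on artifact-free data the subtraction removes brain signal
  res0 <- quiet(method_pca_regression(clean$data, 1024, n_pcs = 3,
                                      removal_config(), seed = 11))
  expect_lt(mean_correlation(res0$cleaned, clean$data), 0.99)
})

test_that("apply_method dispatches and validates", {
  set.seed(212)
  x <- matrix(rnorm(9 * 1024), 9)
  expect_identical(apply_method("none", x, 1024)$cleaned, x)
  expect_error(apply_method("proposed", x, 1024), "needs a subspace plan")
  expect_error(apply_method("Z", x, 1024), "unknown method")
})
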