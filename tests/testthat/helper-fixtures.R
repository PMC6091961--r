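# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no binary fixtures.

# Small deterministic montage: n points on the upper unit hemisphere.
hemi_montage <- function(n, prefix = "E") {
  montage(sprintf("%s%02d", prefix, seq_len(n)),
          subica:::fibonacci_hemisphere(n))
}

# A patch of n adjacent electrodes from the packaged high-density layout,
# centered on the frontal-most electrode (the low-dimensional "adjacent
# electrodes" scenario where full-channel ICA is expected to work).
patch_montage <- function(n = 9) {
  hd <- standard_montage("hd111")
  d <- montage_distances(hd)
  idx <- neighbor_indices(d, which.max(hd$coords[, 1]), n)
  montage(hd$labels[idx], hd$coords[idx, , drop = FALSE])
}

# Amari performance index of P = W_est %*% mixing: 0 for a perfect
# (scaled/permuted) inverse, larger for residual mixing.
amari_index <- function(P) {
  A <- abs(P)
  n <- nrow(A)
  row_term <- sum(rowSums(A / apply(A, 1, max)) - 1)
  col_term <- sum(colSums(t(t(A) / apply(A, 2, max))) - 1)
  (row_term + col_term) / (2 * n * (n - 1))
}

# Greedy matching of estimated components to true sources by absolute
# correlation; returns the matched |correlation| per true source.
match_components <- function(S_est, S_true) {
  C <- abs(stats::cor(t(S_est), t(S_true)))
  out <- numeric(ncol(C))
  for (j in seq_len(ncol(C))) {
    i <- which.max(C[, j])
    out[j] <- C[i, j]
    C[i, ] <- -1
  }
  out
}

# Uncentered correlation of one channel pair (independent oracle for
# mean_correlation).
uncentered_r <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

quiet <- function(expr) suppressWarnings(expr)
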