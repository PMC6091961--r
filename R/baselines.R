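#' @name baselines
#' @title Reference artifact-removal methods
#'
#' @description
#' The comparison methods the subspace approach is benchmarked against:
#'
#' * **A** — plain full-channel FastICA with component classification and
#'   reconstruction; no overlearning suppression.
#' * **Ba** — 1 Hz fixed high-pass filtering before the ICA of method A.
#' * **Bb** — AR-model-based high-pass (prediction-error whitening) before the
#'   ICA of method A. The original filter design is not fully specified by its
#'   sources; this implementation fits per-channel AR models by least squares
#'   and applies the channel-averaged prediction-error filter, and is
#'   documented as an interpretation.
#' * **C** — PCA reduction to `n_pcs` components, ICA there, classification,
#'   reconstruction through the retained PC basis (rank is always reduced).
#' * **D** — ICA on the top `n_pcs` (default 3) principal components, then
#'   least-squares subtraction of those components from every channel; no
#'   classification.
#'
#' For Ba/Bb the separation matrix is estimated on the filtered data but the
#' removal operator is applied to the unfiltered data: the filtering aids
#' separation and is not meant to distort the output.
#'
#' All functions take and return an M x N matrix (channels in rows).
NULL

# Shared core of A/Ba/Bb/C: full ICA on `x_est`, classification of its
# components, removal operator applied to `x_apply`.
ica_clean_operator <- function(x_est, x_apply, fs, config, seed) {
  sep <- separate_subspace(x_est, config$ica, seed)
  cls <- config$classifier(sep$S, fs, config$bands)
  Cmat <- sep$B_inv %*% (cls$keep * sep$B)
  list(cleaned = Cmat %*% x_apply, n_removed = sum(!cls$keep),
       alpha = cls$alpha)
}

#' @rdname baselines
#' @param x M x N numeric matrix (channels in rows).
#' @param fs sampling rate in Hz.
#' @param config a [removal_config()] (classifier bands, threshold and ICA
#'   settings are taken from it).
#' @param seed integer seed.
#' @return list with `cleaned` (M x N matrix) plus method diagnostics.
#' @export
method_plain_ica <- function(x, fs, config = removal_config(), seed = config$seed) {
  ica_clean_operator(x, x, fs, config, seed)
}

#' @rdname baselines
#' @param cutoff high-pass cut-off in Hz (default 1).
#' @export
method_highpass_fixed <- function(x, fs, config = removal_config(),
                                  seed = config$seed, cutoff = 1) {
  if (cutoff >= fs / 2) stop_invalid("cutoff must be below Nyquist")
  hp <- signal::butter(4, cutoff / (fs / 2), type = "high")
  xf <- t(apply(x, 1, function(ch) zerophase_filter(hp, ch)))
  ica_clean_operator(xf, x, fs, config, seed)
}

#' @rdname baselines
#' @param ar_order AR model order for the prediction-error filter (default 8).
#' @export
method_highpass_ar <- function(x, fs, config = removal_config(),
                               seed = config$seed, ar_order = 8L) {
  coefs <- vapply(seq_len(nrow(x)), function(i) {
    fit <- tryCatch(stats::ar(x[i, ], aic = FALSE, order.max = ar_order,
                              method = "ols", demean = TRUE),
                    error = function(e) NULL)
    a <- if (is.null(fit)) numeric(0) else as.numeric(fit$ar)
    c(a, numeric(ar_order - length(a)))
  }, numeric(ar_order))
  abar <- rowMeans(matrix(coefs, nrow = ar_order))
  # common prediction-error (whitening) FIR filter e[n] = x[n] - sum a_i x[n-i]
  xf <- t(apply(x, 1, function(ch)
    as.numeric(signal::filter(c(1, -abar), 1, ch))))
  ica_clean_operator(xf, x, fs, config, seed)
}

# Top-n principal directions of the channel covariance.
top_pcs <- function(x, n_pcs) {
  mu <- rowMeans(x)
  xc <- x - mu
  e <- eigen(tcrossprod(xc) / ncol(x), symmetric = TRUE)
  list(U = e$vectors[, seq_len(n_pcs), drop = FALSE], mean = mu, centered = xc)
}

#' @rdname baselines
#' @param n_pcs number of principal components retained (method C) or
#'   separated and regressed out (method D, default 3).
#' @export
method_pca_reduce <- function(x, fs, n_pcs, config = removal_config(),
                              seed = config$seed) {
  if (n_pcs < 2L || n_pcs > nrow(x))
    stop_invalid("n_pcs must be between 2 and the channel count")
  p <- top_pcs(x, n_pcs)
  y <- crossprod(p$U, p$centered)               # n_pcs x N
  res <- ica_clean_operator(y, y, fs, config, seed)
  list(cleaned = p$U %*% res$cleaned + p$mean, n_removed = res$n_removed,
       alpha = res$alpha)
}

#' @rdname baselines
#' @export
method_pca_regression <- function(x, fs, n_pcs = 3L, config = removal_config(),
                                  seed = config$seed) {
  if (n_pcs < 1L || n_pcs > nrow(x))
    stop_invalid("n_pcs must be between 1 and the channel count")
  p <- top_pcs(x, n_pcs)
  y <- crossprod(p$U, p$centered)
  sep <- separate_subspace(y, config$ica, seed)
  S <- sep$S - rowMeans(sep$S)                  # centered separated components
  beta <- x %*% t(S) %*% solve(tcrossprod(S))
  list(cleaned = x - beta %*% S, n_removed = nrow(S), alpha = NULL)
}

#' Apply a named method to a segment
#'
#' Dispatch helper used by the benchmark: `"none"` (pass-through),
#' `"proposed"` (the subspace pipeline; needs `plan`), `"A"`, `"Ba"`, `"Bb"`,
#' `"C"` (needs `n_pcs`) or `"D"`.
#'
#' @param method method id string.
#' @param x M x N segment.
#' @param fs sampling rate in Hz.
#' @param config a [removal_config()].
#' @param seed integer seed.
#' @param plan a [build_subspace_plan()] (required for `"proposed"`).
#' @param n_pcs PC count for methods C and D.
#' @return list with at least `cleaned`.
#' @export
apply_method <- function(method, x, fs, config = removal_config(),
                         seed = config$seed, plan = NULL, n_pcs = NULL) {
  switch(method,
    none = list(cleaned = x, n_removed = 0L),
    proposed = {
      if (is.null(plan)) stop_invalid("method 'proposed' needs a subspace plan")
      r <- remove_artifacts_segment(x, fs, plan, config, seed)
      list(cleaned = r$cleaned, n_removed = sum(r$removed_counts),
           effective_rank = r$effective_rank)
    },
    A = method_plain_ica(x, fs, config, seed),
    Ba = method_highpass_fixed(x, fs, config, seed),
    Bb = method_highpass_ar(x, fs, config, seed),
    C = method_pca_reduce(x, fs, n_pcs %||% 12L, config, seed),
    D = method_pca_regression(x, fs, n_pcs %||% 3L, config, seed),
    stop_invalid("unknown method '", method, "'"))
}
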