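#' ICA engine configuration
#'
#' @param contrast contrast nonlinearity for FastICA: `"tanh"` (log-cosh
#'   negentropy approximation, the robust default), `"cube"` (kurtosis) or
#'   `"gauss"`.
#' @param max_iter maximum fixed-point iterations per start.
#' @param tol convergence tolerance on `max_i |1 - |<w_new, w_old>||`.
#' @param var_tol relative eigenvalue tolerance below which whitening drops a
#'   direction (dimension reduction only for numerically degenerate input).
#' @param n_restarts extra random restarts attempted when a run fails outright.
#' @param restart_tol restarts are only attempted when the best run's smallest
#'   update `delta` is at least this large. On noisy short segments the
#'   iteration typically oscillates near a fixed point (small best delta);
#'   a fresh random start does not fix that, whereas a genuinely failed start
#'   leaves `delta` large.
#' @param stall_iter stop an attempt when the best update size has not
#'   improved for this many consecutive iterations (0 disables). The rotation
#'   with the smallest update seen is returned, so stalling early never
#'   degrades the result.
#' @param stall_factor relative improvement factor that resets the stall
#'   counter.
#' @param alpha slope of the tanh contrast.
#' @return list of class `ica_config`.
#' @export
ica_config <- function(contrast = c("tanh", "cube", "gauss"), max_iter = 500L,
                       tol = 1e-5, var_tol = 1e-10, n_restarts = 3L,
                       restart_tol = 0.1, stall_iter = 50L,
                       stall_factor = 0.98, alpha = 1) {
  contrast <- match.arg(contrast)
  stopifnot(max_iter >= 1, tol > 0, var_tol >= 0, n_restarts >= 0,
            restart_tol >= 0, stall_iter >= 0, stall_factor > 0)
  structure(list(contrast = contrast, max_iter = as.integer(max_iter),
                 tol = tol, var_tol = var_tol,
                 n_restarts = as.integer(n_restarts),
                 restart_tol = restart_tol, stall_iter = as.integer(stall_iter),
                 stall_factor = stall_factor, alpha = alpha),
            class = "ica_config")
}

#' PCA pre-whitening
#'
#' Centers each channel and linearly transforms the data so the sample
#' covariance is the identity. Directions whose eigenvalue falls below
#' `var_tol` times the largest are dropped, so rank-deficient input yields
#' fewer whitened dimensions than channels.
#'
#' @param X d x N numeric matrix (channels in rows).
#' @param var_tol relative eigenvalue cut-off.
#' @return list of class `whitening` with `mean` (length d), `transform`
#'   (d' x d), `inverse` (d x d'), `values` (retained eigenvalues) and `Z`
#'   (the whitened d' x N data).
#' @export
whiten <- function(X, var_tol = 1e-10) {
  if (!is_finite_matrix(X)) stop_invalid("whiten: input must be a finite numeric matrix")
  d <- nrow(X); N <- ncol(X)
  if (all(X == 0)) stop_invalid("whiten: input is identically zero (degenerate)")
  if (N <= d)
    warning("whiten: fewer samples (", N, ") than channels (", d,
            "); estimates will be unreliable", call. = FALSE)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / N
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > max(var_tol * e$values[1], 0)
  if (!any(keep)) stop_invalid("whiten: covariance has no positive eigenvalues")
  V <- e$vectors[, keep, drop = FALSE]
  lam <- e$values[keep]
  K <- (1 / sqrt(lam)) * t(V)           # d' x d
  Kinv <- V * rep(sqrt(lam), each = nrow(V))  # d x d'
  structure(list(mean = mu, transform = K, inverse = Kinv, values = lam,
                 Z = K %*% Xc),
            class = "whitening")
}

# Orthogonal polar factor: the symmetric-decorrelation step of parallel
# FastICA, W <- (W W^T)^{-1/2} W.
sym_orth <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Fixed-point FastICA rotation on whitened data
#'
#' Parallel (symmetric) FastICA: all rows of the orthonormal rotation `W` are
#' updated jointly and re-orthonormalized each iteration, so the result does
#' not depend on component order. On non-convergence the best run is returned
#' with `converged = FALSE` and a warning; up to `n_restarts` fresh random
#' orthogonal initializations are tried first when the run failed outright
#' (final update above `restart_tol`).
#'
#' @param Z whitened d' x N matrix (see [whiten()]).
#' @param config an [ica_config()].
#' @param seed integer seed; the run is deterministic given `Z` and `seed`.
#' @return list with `W` (d' x d' orthonormal), `n_iter`, `converged`,
#'   `delta` (final update size).
#' @export
fastica <- function(Z, config = ica_config(), seed = 1L) {
  stopifnot(is_finite_matrix(Z))
  d <- nrow(Z)
  cidx <- match(config$contrast, c("tanh", "cube", "gauss")) - 1L
  best <- NULL
  for (attempt in 0:config$n_restarts) {
    W0 <- run_seeded(derive_seed(seed, attempt),
                     sym_orth(matrix(stats::rnorm(d * d), d, d)))
    run <- .fastica_core(Z, W0, config$max_iter, config$tol, cidx,
                         config$alpha, config$stall_iter, config$stall_factor)
    if (is.null(best) || run$delta < best$delta) best <- run
    if (best$converged || best$delta < config$restart_tol) break
  }
  if (!best$converged)
    warning("FastICA did not converge within ", config$max_iter,
            " iterations (final delta ", signif(best$delta, 3), ")",
            call. = FALSE)
  best
}

#' Separate one subspace into independent components
#'
#' Whitens the subspace signals, runs [fastica()], and composes the separation
#' matrix `B = W K` with its reconstruction inverse `B_inv = K^{-1} W^T`
#' (a pseudoinverse when whitening dropped rank). With all components
#' retained, `B_inv %*% S + mean` reproduces the input up to the retained
#' subspace.
#'
#' @param X L x N subspace data (channels in rows).
#' @param config an [ica_config()].
#' @param seed integer seed.
#' @return list of class `separation_model`: `B` (d' x L), `B_inv` (L x d'),
#'   `mean`, `S` (d' x N components), `n_iter`, `converged`.
#' @export
separate_subspace <- function(X, config = ica_config(), seed = 1L) {
  w <- tryCatch(whiten(X, config$var_tol), error = function(e)
    stop_invalid("separate_subspace: ", conditionMessage(e)))
  fa <- fastica(w$Z, config, seed)
  B <- fa$W %*% w$transform
  B_inv <- w$inverse %*% t(fa$W)
  structure(list(B = B, B_inv = B_inv, mean = w$mean, S = fa$W %*% w$Z,
                 n_iter = fa$n_iter, converged = fa$converged),
            class = "separation_model")
}

#' Reconstruct subspace signals from (possibly masked) components
#'
#' @param model a `separation_model` from [separate_subspace()].
#' @param S components to reconstruct from (defaults to the model's own).
#' @return L x N matrix.
#' @export
reconstruct_subspace <- function(model, S = model$S) {
  model$B_inv %*% S + model$mean
}
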