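#' Removal pipeline configuration
#'
#' @param L subspace dimension (default 12, the recommended value; see
#'   [build_subspace_plan()]).
#' @param threshold classifier decision threshold; overrides the one in
#'   `bands` when given.
#' @param bands a [band_definition()].
#' @param seg_len_s segment length in seconds for [process_record()].
#' @param ica an [ica_config()].
#' @param seed master seed; all per-segment / per-subspace seeds derive from it.
#' @param hp1 apply a 1 Hz zero-phase high-pass to the record before
#'   processing (off by default; records are commonly already high-passed).
#' @param materialize_operator keep the M x M operator `D` of every segment
#'   for diagnostics (effective-rank computation needs it).
#' @param energy_fraction fraction of singular-value energy defining the
#'   effective rank of `D`.
#' @param classifier component classifier, by default [classify_components()];
#'   any function `(S, fs, bands) -> list(keep=, alpha=)` may be plugged in.
#' @return list of class `removal_config`.
#' @export
removal_config <- function(L = 12L, threshold = NULL, bands = band_definition(),
                           seg_len_s = 1.0, ica = ica_config(), seed = 1L,
                           hp1 = FALSE, materialize_operator = TRUE,
                           energy_fraction = 0.99,
                           classifier = classify_components) {
  if (!is.null(threshold)) bands$threshold <- threshold
  stopifnot(seg_len_s > 0, energy_fraction > 0, energy_fraction <= 1)
  structure(list(L = as.integer(L), bands = bands, seg_len_s = seg_len_s,
                 ica = ica, seed = as.integer(seed), hp1 = hp1,
                 materialize_operator = materialize_operator,
                 energy_fraction = energy_fraction, classifier = classifier),
            class = "removal_config")
}

# Core of the method for one segment, channel sets deduplicated: the operator
# C_k = B_k^{-1} Q_k B_k depends only on the (unordered) channel set of
# subspace k, so each unique set is separated and classified once and its
# contribution weighted by multiplicity. Strictly linear: x_clean = P+ C P x.
segment_operator <- function(x, fs, plan, config, seed) {
  M <- nrow(x); N <- ncol(x)
  keys <- vapply(plan$neighbor_lists,
                 function(i) paste(sort(i), collapse = ","), character(1))
  out <- matrix(0, M, N)
  D <- if (config$materialize_operator) matrix(0, M, M) else NULL
  removed_by_key <- integer(0)
  alphas <- list()
  for (key in unique(keys)) {
    sids <- as.integer(strsplit(key, ",")[[1]])
    mult <- sum(keys == key)
    sub_seed <- derive_seed(seed, min(sids))
    sep <- separate_subspace(x[sids, , drop = FALSE], config$ica, sub_seed)
    cls <- config$classifier(sep$S, fs, config$bands)
    Cmat <- sep$B_inv %*% (cls$keep * sep$B)
    out[sids, ] <- out[sids, ] + mult * (Cmat %*% x[sids, , drop = FALSE])
    if (!is.null(D)) D[sids, sids] <- D[sids, sids] + mult * Cmat
    removed_by_key[key] <- sum(!cls$keep)
    alphas[[key]] <- cls$alpha
  }
  out <- out / plan$counts
  if (!is.null(D)) D <- D / plan$counts
  list(cleaned = out, D = D,
       removed_counts = unname(removed_by_key[keys]),
       alphas = unlist(alphas, use.names = FALSE))
}

#' Remove muscular artifacts from one segment
#'
#' Projects the segment into the electrode-neighborhood subspaces of `plan`,
#' separates each subspace with FastICA, zeroes components classified as
#' muscular artifacts, and recombines the subspaces through the pseudoinverse
#' of the stacked projection. The whole transform is the linear operator
#' `D = P^+ C P`; when no component is removed every per-subspace operator is
#' the identity and the segment passes through undistorted.
#'
#' @param x M x N numeric matrix (channels in rows), one segment.
#' @param fs sampling rate in Hz.
#' @param plan a [build_subspace_plan()] for the same M channels.
#' @param config a [removal_config()].
#' @param seed segment seed (defaults to the config master seed).
#' @return list of class `segment_result`: `cleaned` (M x N), `D` (M x M or
#'   NULL), `removed_counts` (per subspace), `alphas` (all component
#'   statistics), `effective_rank` (99%-energy singular-value count of `D`).
#' @export
remove_artifacts_segment <- function(x, fs, plan, config = removal_config(),
                                     seed = config$seed) {
  stopifnot(inherits(plan, "subspace_plan"))
  if (!is_finite_matrix(x)) stop_invalid("segment must be a finite numeric matrix")
  if (nrow(x) != plan$M)
    stop_invalid("segment has ", nrow(x), " channels but plan expects ", plan$M)
  if (all(x == 0)) {
    warning("segment is identically zero; returned unchanged", call. = FALSE)
    return(structure(list(cleaned = x, D = diag(plan$M),
                          removed_counts = integer(plan$M), alphas = numeric(0),
                          effective_rank = plan$M),
                     class = "segment_result"))
  }
  res <- segment_operator(x, fs, plan, config, seed)
  res$effective_rank <- if (!is.null(res$D)) {
    operator_rank_count(res$D, config$energy_fraction)
  } else NA_integer_
  structure(res, class = "segment_result")
}

#' Remove muscular artifacts from a full record, segment by segment
#'
#' Splits the record into non-overlapping segments of `seg_len_s` seconds and
#' applies [remove_artifacts_segment()] to each; the EMG mixing is only
#' near-stationary over a second or so, which is why short segments are the
#' operating unit. A trailing partial segment is processed if it is at least
#' half a segment long, otherwise passed through unchanged with a warning.
#'
#' @param record an [eeg_record()].
#' @param m an [montage()] whose labels resolve the record's channels, or a
#'   ready-made [build_subspace_plan()].
#' @param config a [removal_config()].
#' @return object of class `removal_result`: `cleaned` (an [eeg_record()]),
#'   `segments` (per-segment `segment_result`s), `removed_total`,
#'   `effective_ranks`.
#' @export
process_record <- function(record, m, config = removal_config()) {
  stopifnot(inherits(record, "eeg_record"))
  if (inherits(m, "subspace_plan")) {
    plan <- m
  } else {
    idx <- align_record_montage(record, m)
    plan <- build_subspace_plan(
      montage(m$labels[idx], m$coords[idx, , drop = FALSE]), config$L)
  }
  x <- record$data
  if (config$hp1) {
    hp <- signal::butter(4, 1 / (record$fs / 2), type = "high")
    x <- t(apply(x, 1, function(ch) zerophase_filter(hp, ch)))
  }
  N <- ncol(x)
  nseg_samp <- max(1L, round(config$seg_len_s * record$fs))
  starts <- seq(1L, N, by = nseg_samp)
  segments <- vector("list", length(starts))
  cleaned <- x
  for (si in seq_along(starts)) {
    i0 <- starts[si]
    i1 <- min(N, i0 + nseg_samp - 1L)
    len <- i1 - i0 + 1L
    if (len < nseg_samp / 2 && si > 1L) {
      warning("trailing partial segment of ", len,
              " samples passed through unprocessed", call. = FALSE)
      segments[[si]] <- NULL
      next
    }
    seg_seed <- derive_seed(config$seed, si)
    res <- remove_artifacts_segment(x[, i0:i1, drop = FALSE], record$fs, plan,
                                    config, seg_seed)
    cleaned[, i0:i1] <- res$cleaned
    segments[[si]] <- res
  }
  done <- !vapply(segments, is.null, logical(1))
  structure(list(
    cleaned = eeg_record(cleaned, record$fs, record$labels),
    segments = segments[done],
    removed_total = sum(vapply(segments[done],
                               function(s) sum(s$removed_counts), numeric(1))),
    effective_ranks = vapply(segments[done],
                             function(s) as.numeric(s$effective_rank %||% NA),
                             numeric(1))),
    class = "removal_result")
}

#' @export
print.removal_result <- function(x, ...) {
  cat("<removal_result> ", length(x$segments), " segment(s), ",
      x$removed_total, " component(s) zeroed, mean effective rank ",
      round(mean(x$effective_ranks, na.rm = TRUE), 1), "\n", sep = "")
  invisible(x)
}

#' Effective rank of the removal operator
#'
#' The number of largest singular values whose cumulative energy reaches
#' `energy_fraction` of the total. Energy is the squared singular value by
#' default ("absolute" uses the plain values).
#'
#' @param D square numeric matrix.
#' @param energy_fraction fraction in (0, 1], default 0.99.
#' @param energy `"squared"` or `"absolute"`.
#' @return integer count.
#' @export
operator_rank_count <- function(D, energy_fraction = 0.99,
                                energy = c("squared", "absolute")) {
  energy <- match.arg(energy)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  sv <- svd(D, nu = 0, nv = 0)$d
  e <- if (energy == "squared") sv^2 else sv
  if (sum(e) == 0) return(0L)
  as.integer(which(cumsum(e) >= energy_fraction * sum(e) - 1e-12)[1])
}
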