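#' Average channel correlation between a reconstruction and the clean truth
#'
#' For each channel the uncentered correlation
#' `sum(x_rec * x_clean) / sqrt(sum(x_rec^2) * sum(x_clean^2))` is computed
#' and the channel values averaged. Uncentered correlation is used because
#' the signals of interest are high-passed and effectively zero-mean; a
#' centered (Pearson) variant is available via `centered = TRUE`. A channel
#' with zero reconstructed norm contributes 0; a channel with zero clean norm
#' is skipped; both warn.
#'
#' @param x_rec,x_clean M x N numeric matrices of identical shape.
#' @param centered subtract channel means first (default FALSE).
#' @return scalar `r` in `[-1, 1]`.
#' @export
mean_correlation <- function(x_rec, x_clean, centered = FALSE) {
  if (!identical(dim(x_rec), dim(x_clean)))
    stop_invalid("reconstruction and clean data must have identical shape")
  if (centered) {
    x_rec <- x_rec - rowMeans(x_rec)
    x_clean <- x_clean - rowMeans(x_clean)
  }
  n_rec <- rowSums(x_rec^2)
  n_cln <- rowSums(x_clean^2)
  usable <- n_cln > 0
  if (!all(usable))
    warning(sum(!usable), " channel(s) with zero clean norm skipped",
            call. = FALSE)
  if (any(n_rec[usable] == 0))
    warning("channel(s) with zero reconstructed norm contribute r = 0",
            call. = FALSE)
  num <- rowSums(x_rec * x_clean)
  r_ch <- ifelse(n_rec > 0, num / sqrt(pmax(n_rec, .Machine$double.xmin) * n_cln), 0)
  mean(r_ch[usable])
}

# Normalize a benchmark method spec: either an id string or
# list(method=, n_pcs=). Returns list(id=, method=, n_pcs=).
normalize_method_spec <- function(spec) {
  if (is.character(spec)) spec <- list(method = spec)
  id <- spec$id %||%
    if (is.null(spec$n_pcs)) spec$method else
      paste0(spec$method, spec$n_pcs)
  list(id = id, method = spec$method, n_pcs = spec$n_pcs)
}

#' Run the simulation benchmark
#'
#' For each trial a fresh clean record and artifact record are simulated and
#' mixed at each `xi`; every method sees the identical mixture, and the
#' reconstruction is scored against the clean truth with [mean_correlation()].
#' A `"none"` row (the unprocessed mixture) is always included.
#'
#' @param methods list of method specs: id strings (`"proposed"`, `"A"`,
#'   `"Ba"`, `"Bb"`) or `list(method = "C", n_pcs = 12)` style lists.
#' @param xi_list numeric vector of energy ratios (e.g. `c(0, 1, 4)`).
#' @param n_trials trials per `xi` (default 100; desk scale).
#' @param m an [montage()] (default the packaged 10-20 layout).
#' @param config a [removal_config()].
#' @param seed master seed.
#' @param duration_s,fs trial length and sampling rate.
#' @param sim_args list with optional `clean_args` / `emg_args` for
#'   [simulate_trial()].
#' @return data.frame of class `benchmark_result` with columns `method`, `xi`,
#'   `r_bar`, `sigma`, `n_trials`, `n_failed`. Attributes: `"r_trials"`
#'   (named list of per-trial r vectors, keyed `method@xi`) and
#'   `"effective_ranks"` (per-trial mean effective rank of the proposed
#'   method's operator, per xi).
#' @export
run_benchmark <- function(methods = list("proposed", "A"),
                          xi_list = c(0, 1, 4), n_trials = 100L,
                          m = standard_montage("1020"),
                          config = removal_config(), seed = 1L,
                          duration_s = 1, fs = 1024, sim_args = list()) {
  stopifnot(n_trials >= 1)
  specs <- c(list(list(method = "none", id = "none")), lapply(methods, normalize_method_spec))
  specs <- specs[!duplicated(vapply(specs, `[[`, "", "id"))]
  needs_plan <- any(vapply(specs, function(s) s$method == "proposed", logical(1)))
  plan <- if (needs_plan) build_subspace_plan(m, config$L) else NULL
  r <- array(NA_real_, c(n_trials, length(specs), length(xi_list)),
             dimnames = list(NULL, vapply(specs, `[[`, "", "id"), xi_list))
  ranks <- matrix(NA_real_, n_trials, length(xi_list))
  for (t in seq_len(n_trials)) {
    trial_seed <- derive_seed(seed, t)
    for (xi_i in seq_along(xi_list)) {
      gt <- do.call(simulate_trial,
                    c(list(m = m, xi = xi_list[xi_i], duration_s = duration_s,
                           fs = fs, seed = trial_seed), sim_args))
      for (s_i in seq_along(specs)) {
        sp <- specs[[s_i]]
        res <- tryCatch(
          apply_method(sp$method, gt$mixed$data, fs, config,
                       seed = derive_seed(trial_seed, s_i, xi_i),
                       plan = plan, n_pcs = sp$n_pcs),
          error = function(e) NULL)
        if (is.null(res)) next
        r[t, s_i, xi_i] <- mean_correlation(res$cleaned, gt$clean$data)
        if (sp$method == "proposed" && !is.null(res$effective_rank))
          ranks[t, xi_i] <- res$effective_rank
      }
    }
  }
  rows <- expand.grid(s_i = seq_along(specs), xi_i = seq_along(xi_list))
  out <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    s_i <- rows$s_i[i]; xi_i <- rows$xi_i[i]
    v <- r[, s_i, xi_i]
    data.frame(method = specs[[s_i]]$id, xi = xi_list[xi_i],
               r_bar = mean(v, na.rm = TRUE),
               sigma = if (sum(!is.na(v)) > 1) stats::sd(v, na.rm = TRUE) else 0,
               n_trials = sum(!is.na(v)), n_failed = sum(is.na(v)))
  }))
  class(out) <- c("benchmark_result", "data.frame")
  attr(out, "r_trials") <- r
  attr(out, "effective_ranks") <- ranks
  out
}

#' Sweep the subspace dimension L
#'
#' Benchmarks the proposed method alone across subspace dimensions on freshly
#' simulated trials (same data for every L within a trial). Values of `L`
#' above the channel count are clamped to it with a warning (at `L = M` the
#' method coincides with full-channel ICA).
#'
#' @param L_values integer vector of subspace dimensions.
#' @param xi energy ratio for the trials (default 4).
#' @param n_trials trials (default 50).
#' @inheritParams run_benchmark
#' @return data.frame with columns `L`, `r_bar`, `sigma`, `n_trials`.
#' @export
sweep_L <- function(L_values, xi = 4, n_trials = 50L,
                    m = standard_montage("1020"), config = removal_config(),
                    seed = 1L, duration_s = 1, fs = 1024, sim_args = list()) {
  M <- length(m$labels)
  L_values <- as.integer(L_values)
  if (any(L_values > M)) {
    warning("L values above the channel count M = ", M, " clamped to M",
            call. = FALSE)
    L_values <- pmin(L_values, M)
  }
  L_values <- unique(L_values)
  plans <- lapply(L_values, function(L)
    suppressWarnings(build_subspace_plan(m, L)))
  r <- matrix(NA_real_, n_trials, length(L_values))
  for (t in seq_len(n_trials)) {
    trial_seed <- derive_seed(seed, t)
    gt <- do.call(simulate_trial,
                  c(list(m = m, xi = xi, duration_s = duration_s, fs = fs,
                         seed = trial_seed), sim_args))
    for (l_i in seq_along(L_values)) {
      res <- tryCatch(
        remove_artifacts_segment(gt$mixed$data, fs, plans[[l_i]], config,
                                 seed = derive_seed(trial_seed, l_i)),
        error = function(e) NULL)
      if (!is.null(res))
        r[t, l_i] <- mean_correlation(res$cleaned, gt$clean$data)
    }
  }
  out <- data.frame(L = L_values,
                    r_bar = colMeans(r, na.rm = TRUE),
                    sigma = apply(r, 2, stats::sd, na.rm = TRUE),
                    n_trials = colSums(!is.na(r)))
  attr(out, "r_trials") <- r
  out
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: segmentation into `seg_len_s`-second
#' segments with fractional overlap `overlap`, each segment windowed
#' (Hamming by default). One-sided density scaling, so
#' `sum(psd) * df` approximates the signal mean square.
#'
#' @param s numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_len_s segment length in seconds (default 1).
#' @param overlap fractional overlap in `[0, 1)` (default 0.75).
#' @param window `"hamming"`, `"hann"` or `"rect"`.
#' @return list with `freq` (Hz) and `psd` (units^2/Hz).
#' @export
welch_psd <- function(s, fs, seg_len_s = 1, overlap = 0.75,
                      window = c("hamming", "hann", "rect")) {
  window <- match.arg(window)
  s <- as.numeric(s)
  nseg <- max(8L, round(seg_len_s * fs))
  if (length(s) < nseg) stop_invalid("signal shorter than one Welch segment")
  w <- switch(window,
              hamming = 0.54 - 0.46 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)),
              hann = 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)),
              rect = rep(1, nseg))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(s) - nseg + 1L, by = step)
  U <- sum(w^2)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (st in starts) {
    seg <- s[st:(st + nseg - 1L)] * w
    X <- stats::fft(seg)[1:nf]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist for even nseg)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (nseg %% 2 == 0) dbl[nf] <- 1
  list(freq = (0:(nf - 1L)) * fs / nseg, psd = psd * dbl)
}
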