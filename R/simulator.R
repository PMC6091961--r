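#' @name simulator
#' @title Synthetic EEG/EMG ground-truth generator
#'
#' @description
#' Stand-in for a real artifact-free EEG corpus and a boundary-element forward
#' model: brain-like sources are pink (1/f) 1--45 Hz noise, a random subset
#' additionally carrying an 8--12 Hz alpha oscillation, spatially mixed with
#' Gaussian scalp-gain profiles centered at random scalp points. Muscular
#' (EMG-like) sources are 20--300 Hz broadband noise gated by transient burst
#' envelopes and localized near fringe (low-z) electrodes, mimicking cervical
#' and mandibular muscle activity. The Gaussian gain profile is a deliberate
#' simplification of volume conduction; absolute benchmark scores therefore do
#' not transfer to real data, although method *orderings* are expected to.
NULL

# Band-limited noise with amplitude spectrum ~ f^(-slope/2) inside [lo, hi],
# synthesized in the frequency domain with random phases; unit RMS.
band_noise <- function(N, fs, lo, hi, slope = 0) {
  nf <- N %/% 2
  f <- (1:nf) * fs / N
  amp <- ifelse(f >= lo & f <= hi, f^(-slope / 2), 0)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = c(0, amp, numeric(N - nf - 1L)),
                  argument = c(0, phase, numeric(N - nf - 1L)))
  # hermitian symmetry for a real signal
  if (N %% 2 == 0) spec[nf + 1L] <- Re(spec[nf + 1L])
  spec[seq(N, N - nf + 2L)] <- Conj(spec[2:nf])
  x <- Re(stats::fft(spec, inverse = TRUE)) / N
  s <- stats::sd(x)
  if (s == 0) x else x / s
}

# Slow (0.3-2 Hz) amplitude-modulation envelope emulating the waxing and
# waning of cortical rhythms (e.g. alpha spindles); mean 1, always positive.
slow_am <- function(N, fs, depth = 0.7) {
  e <- band_noise(N, fs, lo = 0.3, hi = 2, slope = 0)
  env <- 1 + depth * e / max(abs(e), 1e-12)
  pmax(env, 0)
}

# Gaussian scalp gain of a source at point p over electrode positions; an
# optional second, broader Gaussian adds a weak volume-conducted tail.
gaussian_gains <- function(coords, p, sigma, tail_sigma = NULL,
                           tail_weight = 0) {
  d2 <- rowSums((coords - matrix(p, nrow(coords), 3, byrow = TRUE))^2)
  g <- exp(-d2 / (2 * sigma^2))
  if (tail_weight > 0 && !is.null(tail_sigma))
    g <- g + tail_weight * exp(-d2 / (2 * tail_sigma^2))
  g
}

# Contraction events shared by all muscle sources of one record (a jaw clench
# or head movement activates the mandibular and cervical groups together):
# at least one event, each 0.2-1 s (clipped to the record length).
contraction_events <- function(N, fs, rate = 0.5, burst_range = c(0.2, 1)) {
  dur <- N / fs
  n_bursts <- max(1L, stats::rpois(1, rate * dur))
  ev <- lapply(seq_len(n_bursts), function(b) {
    len_s <- stats::runif(1, burst_range[1], min(burst_range[2], dur))
    len <- min(N, round(len_s * fs))
    list(start = sample.int(max(1L, N - len + 1L), 1), len = len)
  })
  ev
}

# Transient on/off burst envelope with raised-cosine 20 ms ramps for one
# source: the shared events, jittered by up to +-50 ms per source.
burst_envelope <- function(N, fs, events, jitter_s = 0.05) {
  env <- numeric(N)
  ramp_n <- max(2L, round(0.02 * fs))
  ramp <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
  for (e in events) {
    start <- e$start + round(stats::runif(1, -jitter_s, jitter_s) * fs)
    len <- max(2L * ramp_n, e$len)
    start <- min(max(1L, start), N - len + 1L)
    shape <- c(ramp, rep(1, len - 2L * ramp_n), rev(ramp))
    idx <- start:(start + len - 1L)
    env[idx] <- pmax(env[idx], shape)
  }
  env
}

#' Simulate artifact-free (brain-only) EEG
#'
#' @param m an [montage()] defining channel count and positions (unit head
#'   radius assumed).
#' @param duration_s record length in seconds (>= 2 samples' worth).
#' @param fs sampling rate in Hz (default 1024).
#' @param n_sources number of brain-like sources (default 40; surface EEG is
#'   a mixture of many distributed generators).
#' @param seed integer seed; output is deterministic per seed.
#' @param sigma spatial spread of the Gaussian gain, in head radii
#'   (default 0.25).
#' @param snr_db sensor-noise level: ratio of source-mixture power to additive
#'   white sensor noise power, in dB (default 20).
#' @param alpha_prob probability that a source also carries an 8--12 Hz
#'   oscillation (default 0.5).
#' @return an [eeg_record()]; attribute `"sources"` holds the source signals,
#'   gain matrix and source centers.
#' @export
simulate_clean_eeg <- function(m, duration_s = 1, fs = 1024, n_sources = 40L,
                               seed = 1L, sigma = 0.25, snr_db = 20,
                               alpha_prob = 0.5) {
  stopifnot(inherits(m, "eeg_montage"), n_sources >= 2L)
  N <- round(duration_s * fs)
  if (N < 2) stop_invalid("duration too short: need at least 2 samples")
  M <- length(m$labels)
  run_seeded(seed, {
    S <- matrix(0, n_sources, N)
    G <- matrix(0, M, n_sources)
    centers <- matrix(0, n_sources, 3)
    for (j in seq_len(n_sources)) {
      s <- band_noise(N, fs, lo = 1, hi = 45, slope = 1) * slow_am(N, fs)
      if (stats::runif(1) < alpha_prob) {
        f0 <- stats::runif(1, 8, 12)
        ph <- stats::runif(1, 0, 2 * pi)
        s <- s + sqrt(2) * sin(2 * pi * f0 * (0:(N - 1)) / fs + ph) *
          slow_am(N, fs)
      }
      p <- stats::rnorm(3)
      p[3] <- abs(p[3])
      p <- p / sqrt(sum(p^2))
      centers[j, ] <- p
      G[, j] <- gaussian_gains(m$coords, p, sigma)
      S[j, ] <- s
    }
    x <- G %*% S
    noise_sd <- sqrt(mean(x^2) / 10^(snr_db / 10))
    x <- x + matrix(stats::rnorm(M * N, sd = noise_sd), M, N)
    rec <- eeg_record(x, fs, m$labels)
    attr(rec, "sources") <- list(signals = S, gains = G, centers = centers)
    rec
  })
}

# Nominal muscle attachment sites on the unit head (radius 1.05, i.e. in the
# tissue just outside the electrode sphere): cervical sources at the lower
# back/sides of the head, mandibular sources lower-front-lateral. +x is the
# nasion direction. `which` cycles cervical/mandibular according to the 5 + 6
# split of the default 11 sources.
muscle_site <- function(which) {
  if (which == "cervical") {
    az <- pi + stats::runif(1, -0.7, 0.7)        # back of the head
    z <- stats::runif(1, -0.25, -0.05)
  } else {
    az <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 1.1)  # front-lateral
    z <- stats::runif(1, -0.15, 0.0)
  }
  r <- sqrt(1 - z^2)
  1.05 * c(r * cos(az), r * sin(az), z)
}

#' Simulate muscular (EMG-like) artifact signals
#'
#' Default 11 sources (5 cervical, 6 mandibular): broadband
#' 20--min(300, 0.45 fs) Hz noise gated by transient burst envelopes. Sources
#' sit at nominal muscle attachment sites just below the electrode rim (back
#' of the neck, jaw angles), so their Gaussian gains are strongest at the
#' fringe (lowest) electrodes of whatever montage is supplied and fall off
#' towards the vertex.
#'
#' @inheritParams simulate_clean_eeg
#' @param n_sources number of muscle sources (default 11, alternating the
#'   5 cervical / 6 mandibular split).
#' @param sigma spread (head radii) of the sharp local gain peak (default
#'   0.2; muscle potentials reach nearby electrodes without the skull's
#'   spatial low-pass filtering, so the peak is tighter than cortical
#'   topographies).
#' @param tail_sigma,tail_weight spread and relative amplitude of the weak
#'   volume-conducted tail added to each gain profile (defaults 0.6 and 0.3);
#'   set `tail_weight = 0` for purely local profiles.
#' @param burst_range burst duration range in seconds (default 0.2--1).
#' @return an [eeg_record()]; attribute `"sources"` as in
#'   [simulate_clean_eeg()].
#' @export
simulate_emg_artifact <- function(m, duration_s = 1, fs = 1024,
                                  n_sources = 11L, seed = 1L, sigma = 0.2,
                                  tail_sigma = 0.6, tail_weight = 0.3,
                                  burst_range = c(0.2, 1)) {
  stopifnot(inherits(m, "eeg_montage"), n_sources >= 1L)
  N <- round(duration_s * fs)
  if (N < 2) stop_invalid("duration too short: need at least 2 samples")
  M <- length(m$labels)
  hi <- min(300, 0.45 * fs)
  kinds <- rep(c("cervical", "mandibular"),
               c(ceiling(n_sources * 5 / 11), n_sources))[seq_len(n_sources)]
  run_seeded(seed, {
    events <- contraction_events(N, fs, burst_range = burst_range)
    S <- matrix(0, n_sources, N)
    G <- matrix(0, M, n_sources)
    centers <- matrix(0, n_sources, 3)
    for (j in seq_len(n_sources)) {
      S[j, ] <- band_noise(N, fs, lo = 20, hi = hi, slope = 0) *
        burst_envelope(N, fs, events)
      p <- muscle_site(kinds[j])
      centers[j, ] <- p
      G[, j] <- gaussian_gains(m$coords, p, sigma, tail_sigma, tail_weight)
    }
    x <- G %*% S
    rec <- eeg_record(x, fs, m$labels)
    attr(rec, "sources") <- list(signals = S, gains = G, centers = centers,
                                 kinds = kinds)
    rec
  })
}

#' Mix clean EEG with artifacts at a controlled energy ratio
#'
#' Forms `mixed = clean + eta * artifact` with
#' `eta = sqrt(xi * E_clean / E_artifact)` so that the energy of the scaled
#' artifact is exactly `xi` times the energy of the clean record: `xi = 0`
#' gives artifact-free data, `xi = 1` equal energies, `xi = 4` artifacts four
#' times stronger.
#'
#' @param clean,artifact [eeg_record()]s of identical shape and rate.
#' @param xi non-negative energy-ratio parameter.
#' @return list of class `eeg_mixture`: `clean`, `artifact`, `mixed`
#'   ([eeg_record()]s), `xi`, `eta`.
#' @export
mix_records <- function(clean, artifact, xi) {
  stopifnot(inherits(clean, "eeg_record"), inherits(artifact, "eeg_record"))
  if (!identical(dim(clean$data), dim(artifact$data)) ||
      clean$fs != artifact$fs)
    stop_invalid("clean and artifact records must have identical shape and fs")
  if (xi < 0) stop_invalid("xi must be non-negative")
  e_clean <- sum(clean$data^2)
  e_art <- sum(artifact$data^2)
  if (xi > 0 && e_art == 0)
    stop_invalid("artifact record has zero energy; cannot scale to xi > 0")
  eta <- if (xi == 0) 0 else sqrt(xi * e_clean / e_art)
  mixed <- eeg_record(clean$data + eta * artifact$data, clean$fs, clean$labels)
  structure(list(clean = clean, artifact = artifact, mixed = mixed,
                 xi = xi, eta = eta),
            class = "eeg_mixture")
}

#' Simulate a full ground-truth trial
#'
#' Convenience wrapper: clean EEG and EMG artifacts on the same montage,
#' mixed at `xi`.
#'
#' @inheritParams simulate_clean_eeg
#' @param xi energy-ratio parameter passed to [mix_records()].
#' @param clean_args,emg_args extra arguments for the two generators.
#' @return an `eeg_mixture` (see [mix_records()]).
#' @export
simulate_trial <- function(m, xi, duration_s = 1, fs = 1024, seed = 1L,
                           clean_args = list(), emg_args = list()) {
  clean <- do.call(simulate_clean_eeg,
                   c(list(m = m, duration_s = duration_s, fs = fs,
                          seed = derive_seed(seed, 1)), clean_args))
  art <- do.call(simulate_emg_artifact,
                 c(list(m = m, duration_s = duration_s, fs = fs,
                        seed = derive_seed(seed, 2)), emg_args))
  mix_records(clean, art, xi)
}
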