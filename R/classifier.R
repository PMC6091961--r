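#' Classifier band definition
#'
#' The artifact classifier compares average power in a low band against two
#' high bands. Muscular (EMG) activity is broadband with most energy above
#' ~20 Hz, while brain rhythms concentrate below ~30 Hz, so a low/high power
#' ratio separates the two classes.
#'
#' @param low,high1,high2 pass-band edges in Hz (defaults 3-30, 60-90,
#'   110-140).
#' @param threshold decision threshold `T`; a component with ratio statistic
#'   `alpha < T` is declared a muscular artifact. Default 2.5.
#' @param order Butterworth order per pass (filtering is zero-phase
#'   forward-backward, so the effective order doubles).
#' @return list of class `band_definition`.
#' @export
band_definition <- function(low = c(3, 30), high1 = c(60, 90),
                            high2 = c(110, 140), threshold = 2.5,
                            order = 4L) {
  bands <- list(low = low, high1 = high1, high2 = high2)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
      stop_invalid("band '", nm, "' must be (lo, hi) with 0 < lo < hi")
  }
  if (low[2] > high1[1] || high1[2] > high2[1])
    stop_invalid("bands must be non-overlapping and ascending")
  stopifnot(threshold > 0, order >= 1)
  structure(c(bands, list(threshold = threshold, order = as.integer(order))),
            class = "band_definition")
}

# Shift the upper bands down proportionally when the sampling rate cannot
# represent them; the classifier is designed for fs >= 300 Hz.
adjust_bands_for_fs <- function(bands, fs) {
  nyq <- fs / 2
  if (bands$high2[2] < nyq) return(bands)
  scale <- (0.95 * nyq) / bands$high2[2]
  warning("sampling rate ", fs, " Hz cannot represent the ",
          bands$high2[1], "-", bands$high2[2],
          " Hz band; scaling upper bands by ", signif(scale, 3),
          " (fs >= 300 Hz recommended)", call. = FALSE)
  bands$high1 <- bands$high1 * scale
  bands$high2 <- bands$high2 * scale
  if (bands$low[2] > bands$high1[1]) bands$low[2] <- bands$high1[1]
  bands
}

# Cached zero-phase Butterworth band-pass. Filter design depends only on
# (order, band / nyquist), so designs are reused across the many component
# classifications of a run.
.filter_cache <- new.env(parent = emptyenv())

bandpass_filter <- function(fs, band, order) {
  key <- paste(order, band[1] / fs, band[2] / fs, sep = "|")
  flt <- .filter_cache[[key]]
  if (is.null(flt)) {
    flt <- signal::butter(order, c(band[1], band[2]) / (fs / 2), type = "pass")
    .filter_cache[[key]] <- flt
  }
  flt
}

#' Zero-phase filtering
#'
#' Forward-backward application of an IIR/FIR filter with odd-reflection edge
#' padding and steady-state initial conditions, cancelling the filter's phase
#' response (the effective magnitude response is squared).
#'
#' @param flt a filter object with `b`/`a` coefficients (e.g.
#'   [signal::butter()]).
#' @param x numeric vector.
#' @return filtered vector of the same length.
#' @export
zerophase_filter <- function(flt, x) {
  as.numeric(.filtfilt_core(as.numeric(flt$b), as.numeric(flt$a),
                            as.numeric(x)))
}

#' Average power of a signal in a frequency band
#'
#' Band-pass filters with a zero-phase (forward-backward) Butterworth filter
#' and returns the mean square of the result.
#'
#' @param s numeric vector, one component signal.
#' @param fs sampling rate in Hz.
#' @param band `(lo, hi)` pass band in Hz; `hi` must be below Nyquist.
#' @param order Butterworth order per pass.
#' @return scalar average power (signal units squared).
#' @export
band_power <- function(s, fs, band, order = 4L) {
  if (band[2] >= fs / 2)
    stop_invalid("band ", band[1], "-", band[2],
                 " Hz exceeds the Nyquist frequency ", fs / 2, " Hz")
  y <- zerophase_filter(bandpass_filter(fs, band, order), s)
  mean(y^2)
}

# alpha statistic from the three band powers; cap keeps it finite for
# spectrally pure components, zero total power is an artifact sentinel.
alpha_from_powers <- function(p1, p2, p3, cap = 1e6) {
  degenerate <- p1 <= 0 & p2 <= 0 & p3 <= 0
  if (any(degenerate))
    warning(sum(degenerate), " component(s) with (numerically) zero power ",
            "in all bands; classifying as artifact", call. = FALSE)
  r2 <- ifelse(p2 > 0, p1 / p2, cap)
  r3 <- ifelse(p3 > 0, p1 / p3, cap)
  ifelse(degenerate, 0, pmin(pmin(r2, r3), cap))
}

#' Low-to-high band power ratio statistic
#'
#' Computes `alpha = min(P1/P2, P1/P3)` where `P1`, `P2`, `P3` are the average
#' powers in the low and the two high bands. Brain components concentrate
#' power at low frequencies (large alpha); broadband muscular components give
#' alpha below the threshold. The ratio is capped at 1e6 for spectrally pure
#' low-frequency components; an all-but-zero-power component returns 0 (treated
#' as artifact) with a warning.
#'
#' @param s numeric vector, one component signal.
#' @param fs sampling rate in Hz.
#' @param bands a [band_definition()].
#' @return scalar alpha.
#' @export
alpha_ratio <- function(s, fs, bands = band_definition()) {
  bands <- adjust_bands_for_fs(bands, fs)
  alpha_from_powers(band_power(s, fs, bands$low, bands$order),
                    band_power(s, fs, bands$high1, bands$order),
                    band_power(s, fs, bands$high2, bands$order))
}

#' Classify separated components as brain signal or muscular artifact
#'
#' Applies [alpha_ratio()] to each row and compares against the threshold.
#' The returned retention mask is the diagonal of the matrix that zeroes
#' artifact components before reconstruction.
#'
#' @param S components in rows (d' x N).
#' @param fs sampling rate in Hz.
#' @param bands a [band_definition()] (carries the threshold).
#' @return list with `keep` (logical vector, TRUE = brain signal) and `alpha`
#'   (numeric vector of statistics).
#' @export
classify_components <- function(S, fs, bands = band_definition()) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  bands <- adjust_bands_for_fs(bands, fs)
  filters <- lapply(list(bands$low, bands$high1, bands$high2), function(b) {
    flt <- bandpass_filter(fs, b, bands$order)
    list(b = as.numeric(flt$b), a = as.numeric(flt$a))
  })
  P <- .band_power_core(S, filters)
  alpha <- alpha_from_powers(P[, 1], P[, 2], P[, 3])
  list(keep = alpha >= bands$threshold, alpha = alpha,
       band_powers = P)
}
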