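# Index-based channel quality metrics: coefficient of variation, scalp
# coupling index, cardiac peak spectral power and the windowed composite
# quality index used for channel preselection.

#' Coefficient of variation of raw intensity
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation. The
#' conventional rejection rule labels a signal low-quality when CV exceeds
#' `threshold` percent (default 15).
#'
#' @param x numeric intensity series (length >= 2, nonzero mean).
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  if (length(x) < 2) stopf("series too short for CV (need >= 2 samples)")
  m <- mean(x)
  if (m == 0) stopf("zero-mean series: CV undefined")
  100 * stats::sd(x) / m
}

#' Classify a CV value against the rejection threshold
#' @param cv_percent CV in percent.
#' @param threshold rejection threshold in percent (default 15).
#' @return "low" if `cv_percent > threshold`, else "high".
#' @export
cv_classify <- function(cv_percent, threshold = 15) {
  ifelse(cv_percent > threshold, "low", "high")
}

#' Scalp coupling index
#'
#' Zero-lag Pearson correlation between the two wavelength signals of a
#' channel after zero-phase band-pass filtering in the fixed cardiac band
#' 0.5-2.5 Hz and z-normalisation. High values indicate that the cardiac
#' pulsation is shared across wavelengths, i.e. good optode-scalp coupling.
#' Degenerate (zero-variance) inputs return 0 with a warning: a flat,
#' saturated channel carries no cardiac evidence.
#'
#' @param w1,w2 equal-length intensity (or OD) series of the two wavelengths.
#' @param fs sampling rate in Hz.
#' @param band cardiac band in Hz (fixed 0.5-2.5 by convention).
#' @return SCI in `[-1, 1]`.
#' @export
sci <- function(w1, w2, fs, band = c(0.5, 2.5)) {
  if (length(w1) != length(w2)) stopf("wavelength series must have equal length")
  if (stats::sd(w1) == 0 || stats::sd(w2) == 0) {
    warnf("zero variance input (saturated channel); SCI set to 0")
    return(0)
  }
  f1 <- bandpass(w1, fs, band[1], band[2])
  f2 <- bandpass(w2, fs, band[1], band[2])
  s1 <- stats::sd(f1); s2 <- stats::sd(f2)
  if (s1 == 0 || s2 == 0) {
    warnf("zero variance after cardiac-band filtering; SCI set to 0")
    return(0)
  }
  z1 <- (f1 - mean(f1)) / s1
  z2 <- (f2 - mean(f2)) / s2
  mean(z1 * z2) * length(z1) / (length(z1) - 1)
}

#' Classify an SCI value
#' @param sci_value SCI value.
#' @param threshold quality threshold (default 0.75).
#' @return "low" if `sci_value < threshold`, else "high".
#' @export
sci_classify <- function(sci_value, threshold = 0.75) {
  ifelse(sci_value < threshold, "low", "high")
}

#' Cardiac peak spectral power
#'
#' Peak of the normalised power spectrum of the cross-correlation of the two
#' band-filtered, z-normalised wavelength series, within the cardiac band.
#' The cross-correlation of unit-variance series is Fourier transformed and
#' the spectrum scaled to total power one, so the result lies in `[0, 1]`;
#' a shared near-sinusoidal cardiac component concentrates the spectrum at
#' the heart rate and drives the value towards 1. The "peak" is the power in
#' a 3-bin cluster around the spectral argmax: the cross-correlation sequence
#' has a triangular envelope whose leakage splits even a pure tone across
#' neighbouring bins.
#'
#' @inheritParams sci
#' @return normalised peak power in `[0, 1]`.
#' @export
psp <- function(w1, w2, fs, band = c(0.5, 2.5)) {
  if (length(w1) != length(w2)) stopf("wavelength series must have equal length")
  if (stats::sd(w1) == 0 || stats::sd(w2) == 0) {
    warnf("zero variance input (saturated channel); PSP set to 0")
    return(0)
  }
  f1 <- bandpass(w1, fs, band[1], band[2])
  f2 <- bandpass(w2, fs, band[1], band[2])
  s1 <- stats::sd(f1); s2 <- stats::sd(f2)
  if (s1 == 0 || s2 == 0) {
    warnf("zero variance after cardiac-band filtering; PSP set to 0")
    return(0)
  }
  z1 <- (f1 - mean(f1)) / s1
  z2 <- (f2 - mean(f2)) / s2
  n <- length(z1)
  # full biased cross-correlation sequence (lags -(n-1)..(n-1))
  cc <- stats::convolve(z1, z2, conj = TRUE, type = "open") / n
  nl <- length(cc)
  spec <- Mod(stats::fft(cc))^2
  freqs <- (seq_len(nl) - 1) * fs / nl
  pos <- freqs <= fs / 2
  spec <- spec[pos]; freqs <- freqs[pos]
  tot <- sum(spec)
  if (tot == 0) return(0)
  spec <- spec / tot
  in_band <- freqs >= band[1] & freqs <= min(band[2], fs / 2)
  if (!any(in_band)) return(0)
  spec_cluster(spec, which(in_band))
}

# power in the best 3-bin cluster centred on an in-band bin
spec_cluster <- function(spec, band_idx) {
  n <- length(spec)
  max(vapply(band_idx, function(i) {
    sum(spec[max(1, i - 1):min(n, i + 1)])
  }, numeric(1)))
}

# per-window SCI and PSP of a channel; the record is band-filtered once,
# then split into non-overlapping windows
windowed_indices <- function(w1, w2, fs, window_s = 5, band = c(0.5, 2.5)) {
  if (length(w1) != length(w2)) stopf("wavelength series must have equal length")
  win <- floor(window_s * fs)
  n_win <- floor(length(w1) / win)
  if (n_win < 1) stopf("record shorter than one %gs window", window_s)
  f1 <- bandpass(w1, fs, band[1], band[2])
  f2 <- bandpass(w2, fs, band[1], band[2])
  sci_w <- numeric(n_win); psp_w <- numeric(n_win)
  for (k in seq_len(n_win)) {
    idx <- ((k - 1) * win + 1):(k * win)
    # saturated (constant raw) windows carry no cardiac evidence; their
    # filtered residues are identical across wavelengths and would score 1
    if (stats::sd(w1[idx]) == 0 || stats::sd(w2[idx]) == 0) next
    a <- f1[idx]; b <- f2[idx]
    sa <- stats::sd(a); sb <- stats::sd(b)
    if (sa == 0 || sb == 0) next  # degenerate window scores 0/0
    za <- (a - mean(a)) / sa; zb <- (b - mean(b)) / sb
    sci_w[k] <- mean(za * zb) * length(za) / (length(za) - 1)
    cc <- stats::convolve(za, zb, conj = TRUE, type = "open") / length(za)
    spec <- Mod(stats::fft(cc))^2
    nl <- length(cc)
    freqs <- (seq_len(nl) - 1) * fs / nl
    posm <- freqs <= fs / 2
    spec <- spec[posm]; fr <- freqs[posm]
    tot <- sum(spec)
    if (tot > 0) {
      ib <- fr >= band[1] & fr <= min(band[2], fs / 2)
      if (any(ib)) psp_w[k] <- spec_cluster(spec / tot, which(ib))
    }
  }
  data.frame(sci = sci_w, psp = psp_w)
}

#' Windowed composite quality index
#'
#' The channel is split into non-overlapping windows of `window_s` seconds and
#' the CQI is the fraction of windows in which both the SCI and the PSP pass
#' their per-window gates (QT-NIRS-style semantics). Used for preselecting
#' the channels from which the subject's cardiac band is fitted.
#'
#' @inheritParams sci
#' @param window_s window length in seconds (default 5).
#' @param sci_thr per-window SCI gate (default 0.8).
#' @param psp_thr per-window PSP gate (default 0.1).
#' @return fraction of passing windows in `[0, 1]`.
#' @export
cqi <- function(w1, w2, fs, window_s = 5, sci_thr = 0.8, psp_thr = 0.1,
                band = c(0.5, 2.5)) {
  wi <- windowed_indices(w1, w2, fs, window_s, band)
  mean(wi$sci >= sci_thr & wi$psp >= psp_thr)
}

#' All quality indices for one channel
#'
#' Channel-level SCI and PSP are medians over the 5-s windows (robust to
#' transient artifacts, matching windowed channel-pruning practice); the
#' whole-series [sci()] remains available for segment-level baselines.
#'
#' @param w1,w2 wavelength series.
#' @param fs sampling rate (Hz).
#' @param window_s window length (s).
#' @param sci_thr,psp_thr per-window CQI gates.
#' @return list with `cv_percent` (worst of the two wavelengths), `sci`,
#'   `psp` (windowed medians), `cqi`.
#' @export
channel_quality_metrics <- function(w1, w2, fs, window_s = 5, sci_thr = 0.8,
                                    psp_thr = 0.1) {
  wi <- windowed_indices(w1, w2, fs, window_s)
  list(cv_percent = max(coefficient_of_variation(w1), coefficient_of_variation(w2)),
       sci = stats::median(wi$sci),
       psp = stats::median(wi$psp),
       cqi = mean(wi$sci >= sci_thr & wi$psp >= psp_thr))
}
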