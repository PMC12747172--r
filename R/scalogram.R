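# Morlet scalograms and their standardization to 224x224 RGB images with the
# subject's cardiac frequency anchored at a fixed row.

#' Default log-spaced frequency grid for the CWT
#'
#' 12 voices per octave over `[0.2, min(5, 0.95 * fs / 2)]` Hz, descending
#' (highest frequency first: image convention, top row = highest frequency).
#'
#' @param fs sampling rate (Hz).
#' @param fmin,fmax grid limits (Hz).
#' @param voices voices per octave.
#' @return numeric vector of frequencies, descending.
#' @export
cwt_freq_grid <- function(fs, fmin = 0.2, fmax = min(5, 0.95 * fs / 2), voices = 12) {
  if (fmax <= fmin) stopf("empty CWT frequency grid")
  n_oct <- log2(fmax / fmin)
  f <- fmin * 2^(seq(0, n_oct, by = 1 / voices))
  rev(f)
}

#' Band-pass filter a segment in the subject's cardiac band
#'
#' Zero-phase Butterworth band-pass on `[band$low, band$high]`. Very narrow
#' fitted bands are widened to a minimum width (default 0.3 Hz, centred on the
#' band centre) before filtering: an 8-pole filter on a band a few
#' milli-hertz wide is numerically fragile and physiologically meaningless
#' given normal heart-rate variability.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param band a `cardiac_band` (or list with `low`, `high`).
#' @param order Butterworth prototype order.
#' @param min_width_hz minimum filter band width (Hz).
#' @return filtered series.
#' @export
bandpass_cardiac <- function(x, fs, band, order = 4, min_width_hz = 0.3) {
  lo <- band$low; hi <- band$high
  if (!(lo > 0 && hi > lo)) stopf("invalid cardiac band [%g, %g]", lo, hi)
  if (hi >= fs / 2) stopf("cardiac band beyond Nyquist (%g Hz)", fs / 2)
  if (hi - lo < min_width_hz) {
    mid <- (lo + hi) / 2
    lo <- max(mid - min_width_hz / 2, 1e-3)
    hi <- min(mid + min_width_hz / 2, 0.95 * fs / 2)
  }
  bandpass(x, fs, lo, hi, order = order)
}

#' Morlet continuous wavelet transform magnitude
#'
#' Analytic Morlet wavelet (centre-frequency parameter `omega0 = 6`) evaluated
#' in the Fourier domain on a log-spaced frequency grid, with L1-type
#' normalization so a unit-amplitude sinusoid produces a ridge of equal
#' magnitude at every frequency. The signal is zero-padded to the next power
#' of two to limit wrap-around.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid (Hz), descending; default [cwt_freq_grid()].
#' @param omega0 Morlet centre frequency parameter (default 6).
#' @return list of class `fnirs_scalogram`: `magnitude` `[freq x time]`,
#'   `freqs` (descending), `times` (s).
#' @export
cwt_morlet <- function(x, fs, freqs = cwt_freq_grid(fs), omega0 = 6) {
  n <- length(x)
  if (any(freqs >= fs / 2)) stopf("CWT grid extends beyond Nyquist")
  if (n < 4 * fs / min(freqs)) {
    warnf("record shorter than 4 cycles of the lowest CWT frequency")
  }
  nfft <- 2^ceiling(log2(2 * n))
  xf <- stats::fft(c(x, rep(0, nfft - n)))
  w <- 2 * pi * (0:(nfft - 1)) / nfft * fs
  mag <- matrix(0, length(freqs), n)
  for (k in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[k])
    # analytic Morlet: support on positive frequencies only
    psi <- numeric(nfft)
    pos <- which(w > 0 & w <= pi * fs)
    psi[pos] <- exp(-(s * w[pos] - omega0)^2 / 2) * 2
    wt <- stats::fft(xf * psi, inverse = TRUE) / nfft
    mag[k, ] <- Mod(wt[1:n])
  }
  structure(list(magnitude = mag, freqs = freqs, times = (seq_len(n) - 1) / fs),
            class = "fnirs_scalogram")
}

#' Joint min-max normalization of one channel's segment scalograms
#'
#' All segments of a channel share one min and one max (pooled over segments),
#' preserving relative contrast between segments. Constant pooled values map
#' to all-zero output with a warning. Idempotent and order-invariant.
#'
#' @param scalograms list of `fnirs_scalogram` for the segments of one channel.
#' @return list of normalized `fnirs_scalogram` (magnitudes in `[0, 1]`).
#' @export
normalize_segments <- function(scalograms) {
  if (!length(scalograms)) stopf("no scalograms to normalize")
  lo <- min(vapply(scalograms, function(s) min(s$magnitude), numeric(1)))
  hi <- max(vapply(scalograms, function(s) max(s$magnitude), numeric(1)))
  if (hi <= lo) {
    warnf("constant scalogram values across segments; normalized to 0")
    return(lapply(scalograms, function(s) { s$magnitude[] <- 0; s }))
  }
  lapply(scalograms, function(s) {
    s$magnitude <- (s$magnitude - lo) / (hi - lo)
    s
  })
}

#' MATLAB-style jet colormap
#'
#' Piecewise-linear map with breakpoints (0, 0, 0.5) at 0 through deep red
#' (0.5, 0, 0) at 1. Input is clipped to `[0, 1]`.
#'
#' @param v numeric vector/matrix of values.
#' @return matrix with columns r, g, b (one row per input value), in `[0, 1]`.
#' @export
jet_rgb <- function(v) {
  v <- clamp(as.numeric(v), 0, 1)
  bp <- c(0, 0.125, 0.375, 0.625, 0.875, 1)
  r <- stats::approx(bp, c(0, 0, 0, 1, 1, 0.5), v)$y
  g <- stats::approx(bp, c(0, 0, 1, 1, 0, 0), v)$y
  b <- stats::approx(bp, c(0.5, 1, 1, 0, 0, 0), v)$y
  cbind(r = r, g = g, b = b)
}

#' Standardize a normalized scalogram to a 224x224 RGB image
#'
#' The frequency rows are shifted by an integer offset so the row nearest the
#' subject's median cardiac frequency lands on a fixed reference row
#' (default row 30, 1-based from the top); vacated rows are zero-padded and
#' overflow is cropped, then the frequency axis is cropped/padded to
#' `size` rows. The time axis is rescaled to `size` columns by bilinear
#' interpolation on the scalar field, and only then is the jet colormap
#' applied (avoiding colormap interpolation artifacts).
#'
#' @param norm a normalized `fnirs_scalogram` (values in `[0, 1]`).
#' @param band the subject's `cardiac_band`.
#' @param target_row reference row for the cardiac frequency (default 30).
#' @param size output image side (default 224).
#' @return list of class `fnirs_std_image`: `pixels` `[size, size, 3]`,
#'   `field` (the standardized scalar field), `cardiac_row`.
#' @export
align_and_resize <- function(norm, band, target_row = 30, size = 224) {
  stopifnot(inherits(norm, "fnirs_scalogram"))
  f <- norm$freqs
  if (band$cf_median > max(f) || band$cf_median < min(f)) {
    stopf("cardiac frequency %.3f Hz outside the CWT grid [%.3f, %.3f]",
          band$cf_median, min(f), max(f))
  }
  cf_row <- which.min(abs(f - band$cf_median))
  offset <- target_row - cf_row
  nr <- nrow(norm$magnitude)
  shifted <- matrix(0, size, ncol(norm$magnitude))
  src <- seq_len(nr)
  dst <- src + offset
  keep <- dst >= 1 & dst <= size
  shifted[dst[keep], ] <- norm$magnitude[src[keep], ]
  field <- resize_bilinear(shifted, size, size)
  field <- clamp(field, 0, 1)
  px <- array(jet_rgb(field), dim = c(size, size, 3))
  structure(list(pixels = px, field = field, cardiac_row = target_row,
                 cf_median = band$cf_median),
            class = "fnirs_std_image")
}

#' Full scalogram pipeline for one channel of a recording
#'
#' Band-pass in the subject band, Morlet CWT per segment, channel-pooled
#' normalization and standardization of every segment.
#'
#' @param hbo_channel oxyhemoglobin series of one channel (uM).
#' @param fs sampling rate (Hz).
#' @param band subject's `cardiac_band`.
#' @param segments data frame of this channel's segment rows (0-based,
#'   half-open sample intervals).
#' @param size output image side.
#' @param target_row cardiac reference row.
#' @return list of `fnirs_std_image`, one per segment row.
#' @export
channel_scalograms <- function(hbo_channel, fs, band, segments,
                               size = 224, target_row = 30) {
  filt <- bandpass_cardiac(hbo_channel, fs, band)
  scs <- lapply(seq_len(nrow(segments)), function(i) {
    idx <- (segments$start_sample[i] + 1):segments$end_sample[i]
    cwt_morlet(filt[idx], fs)
  })
  scs <- normalize_segments(scs)
  lapply(scs, align_and_resize, band = band, target_row = target_row, size = size)
}

#' Write a standardized image as PNG (requires the png package)
#' @param img an `fnirs_std_image`.
#' @param path output path.
#' @export
write_image_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) stopf("package 'png' not available")
  png::writePNG(img$pixels, path)
  invisible(path)
}
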