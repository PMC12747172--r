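# Subject-specific cardiac band extraction: Welch PSD, Savitzky-Golay
# smoothing, aperiodic (1/f) flattening by cubic fit in dB, prominence-gated
# peak detection, Gaussian peak fitting, channel preselection and the median
# band across best channels.

#' Configuration of the spectral fitting stage
#'
#' @param welch_window_s Welch window length in seconds (default 60 s, i.e.
#'   ~0.017 Hz resolution).
#' @param sg_frame_bins Savitzky-Golay frame length in bins (odd, default 11).
#' @param min_prominence_db prominence gate for retained peaks (default 0.5 dB).
#' @param cqi_relax_step step by which the CQI preselection threshold is
#'   relaxed when no channel passes (default 0.05).
#' @param hr_search_range plausibility range (Hz) for the cardiac candidate
#'   peak; wide by default (0.5-3.5 Hz) to cover infant heart rates.
#' @param fit_range frequency range (Hz) of the aperiodic cubic fit.
#' @param psd_average Welch averaging (`"median"` by default: robust against
#'   motion-burst windows).
#' @return list of class `spectral_fit_config`.
#' @export
spectral_fit_config <- function(welch_window_s = 60, sg_frame_bins = 11,
                                min_prominence_db = 0.5, cqi_relax_step = 0.05,
                                hr_search_range = c(0.5, 3.5),
                                fit_range = c(0.01, Inf),
                                psd_average = "median") {
  structure(list(welch_window_s = welch_window_s, sg_frame_bins = sg_frame_bins,
                 min_prominence_db = min_prominence_db,
                 cqi_relax_step = cqi_relax_step,
                 hr_search_range = hr_search_range, fit_range = fit_range,
                 psd_average = psd_average),
            class = "spectral_fit_config")
}

#' Welch power spectral density in dB
#'
#' Hamming-windowed, mean-detrended, 50%-overlap averaged periodogram
#' (density scaling). Power is returned as `10*log10`, floored at -120 dB so
#' silent signals stay finite.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds.
#' @param overlap fractional overlap (default 0.5).
#' @param floor_db dB floor (default -120).
#' @param average `"mean"` (the classical estimator) or `"median"` across
#'   windows (robust to transient artifacts that would otherwise bury the
#'   cardiac peak under broadband power; used by the band-fitting stage).
#' @return list of class `fnirs_psd` with `freqs` (Hz, DC excluded) and
#'   `power_db`.
#' @export
welch_psd <- function(x, fs, window_s = 60, overlap = 0.5, floor_db = -120,
                      average = c("mean", "median")) {
  average <- match.arg(average)
  nper <- min(floor(window_s * fs), length(x))
  if (nper < 8) stopf("series too short for Welch PSD (window %d samples)", nper)
  step <- max(1, floor(nper * (1 - overlap)))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nper - 1) / (nper - 1))
  scale <- 1 / (fs * sum(w^2))
  pg <- matrix(0, nper, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + nper - 1)]
    seg <- (seg - mean(seg)) * w
    pg[, k] <- Mod(stats::fft(seg))^2
  }
  p <- if (average == "median") {
    apply(pg, 1, stats::median) * scale
  } else {
    rowMeans(pg) * scale
  }
  nfreq <- floor(nper / 2)
  freqs <- (1:nfreq) * fs / nper
  p <- p[2:(nfreq + 1)]
  # one-sided: double everything except Nyquist (present only for even nper)
  dbl <- rep(2, nfreq)
  if (nper %% 2 == 0) dbl[nfreq] <- 1
  p <- p * dbl
  structure(list(freqs = freqs,
                 power_db = pmax(10 * log10(pmax(p, 0)), floor_db),
                 window_s = window_s, fs = fs),
            class = "fnirs_psd")
}

#' Savitzky-Golay smoothing of a PSD
#'
#' Third-order polynomial smoothing of the dB spectrum, preserving peak
#' morphology while suppressing estimation noise.
#'
#' @param psd an `fnirs_psd`.
#' @param frame_bins odd frame length in bins (default 11).
#' @return smoothed `fnirs_psd`.
#' @export
smooth_psd <- function(psd, frame_bins = 11) {
  stopifnot(inherits(psd, "fnirs_psd"))
  if (frame_bins > length(psd$power_db)) stopf("SG frame larger than spectrum")
  psd$power_db <- savgol(psd$power_db, frame_bins, degree = 3)
  psd$sg_frame_bins <- frame_bins
  psd
}

#' Remove the aperiodic 1/f background from a dB spectrum
#'
#' Fits a cubic polynomial in frequency to the dB power over `fit_range` by
#' least squares and subtracts it, leaving a flattened spectrum in which
#' periodic peaks stand out against a ~0 dB baseline. The fit is a two-pass
#' robust fit in the spirit of spectral parameterization: bins more than 1 dB
#' above the first-pass cubic (i.e. peak candidates) are excluded from the
#' second pass so strong peaks do not drag the background estimate.
#'
#' @param psd an `fnirs_psd`.
#' @param fit_range frequency range (Hz) used for the fit; the fitted cubic is
#'   subtracted over the whole grid.
#' @return flattened `fnirs_psd` (with the fit coefficients in `$aperiodic_fit`).
#' @export
flatten_spectrum <- function(psd, fit_range = c(0.01, Inf)) {
  stopifnot(inherits(psd, "fnirs_psd"))
  sel <- psd$freqs >= fit_range[1] & psd$freqs <= fit_range[2]
  if (sum(sel) < 8) stopf("fewer than 8 bins in aperiodic fit range")
  X <- outer(psd$freqs[sel], 0:3, `^`)
  qrX <- qr(X)
  if (qrX$rank < 4) stopf("rank-deficient aperiodic fit")
  beta <- qr.coef(qrX, psd$power_db[sel])
  resid <- psd$power_db[sel] - as.numeric(X %*% beta)
  keep <- resid <= 1  # exclude peak candidates from the background fit
  if (sum(keep) >= 8 && qr(X[keep, , drop = FALSE])$rank == 4) {
    beta <- qr.coef(qr(X[keep, , drop = FALSE]), psd$power_db[sel][keep])
  }
  psd$power_db <- psd$power_db - as.numeric(outer(psd$freqs, 0:3, `^`) %*% beta)
  psd$aperiodic_fit <- beta
  psd
}

peak_prominence <- function(x, i) {
  n <- length(x)
  j <- i - 1; lmin <- x[i]
  while (j >= 1 && x[j] <= x[i]) { lmin <- min(lmin, x[j]); j <- j - 1 }
  j <- i + 1; rmin <- x[i]
  while (j <= n && x[j] <= x[i]) { rmin <- min(rmin, x[j]); j <- j + 1 }
  x[i] - max(lmin, rmin)
}

#' Detect prominent peaks in a flattened spectrum
#'
#' Local maxima over the entire frequency range whose topographic prominence
#' exceeds `min_prominence_db`.
#'
#' @param psd flattened `fnirs_psd`.
#' @param min_prominence_db prominence gate in dB (default 0.5).
#' @return data frame with `index`, `freq`, `height`, `prominence` (possibly
#'   zero rows).
#' @export
detect_peaks <- function(psd, min_prominence_db = 0.5) {
  x <- psd$power_db
  n <- length(x)
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1
  if (!length(cand)) {
    return(data.frame(index = integer(), freq = numeric(), height = numeric(),
                      prominence = numeric()))
  }
  prom <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
  keep <- prom > min_prominence_db
  data.frame(index = cand[keep], freq = psd$freqs[cand[keep]],
             height = x[cand[keep]], prominence = prom[keep])
}

#' Fit a Gaussian to a detected spectral peak
#'
#' Nonlinear least squares of `a * exp(-(f - cf)^2 / (2 sigma^2))` over a
#' window of +/- 3 empirical half-prominence widths around the apex. Widths
#' follow from the fitted sigma: `FWHM = 2 sigma sqrt(2 ln 2)`,
#' `FW10M = 2 sigma sqrt(2 ln 10)`. If the fit fails to converge the
#' empirical widths are used and the result flagged (`fitted = FALSE`).
#'
#' @param psd flattened `fnirs_psd`.
#' @param peak_index bin index of the apex (from [detect_peaks()]).
#' @param prominence peak prominence (dB); recomputed when missing.
#' @return list of class `spectral_peak`: `cf`, `amplitude`, `sigma`, `fwhm`,
#'   `fw10m`, `prominence`, `fitted`.
#' @export
fit_gaussian_peak <- function(psd, peak_index, prominence = NULL) {
  x <- psd$power_db; f <- psd$freqs
  n <- length(x)
  if (is.null(prominence)) prominence <- peak_prominence(x, peak_index)
  half <- x[peak_index] - prominence / 2
  l <- peak_index; while (l > 1 && x[l] > half) l <- l - 1
  r <- peak_index; while (r < n && x[r] > half) r <- r + 1
  half_width_bins <- max(r - l, 2) / 2
  w <- max(5, ceiling(3 * half_width_bins))
  sel <- max(1, peak_index - w):min(n, peak_index + w)
  fw <- f[sel]; yw <- x[sel]
  df_bin <- f[2] - f[1]
  start <- c(a = max(x[peak_index], 0.1), cf = f[peak_index],
             sigma = max(half_width_bins * df_bin / sqrt(2 * log(2)), df_bin / 2))
  sse <- function(p) sum((yw - p[1] * exp(-(fw - p[2])^2 / (2 * p[3]^2)))^2)
  # direct least squares (nls cannot handle the zero-residual case)
  fit <- tryCatch(
    stats::optim(start, sse, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14)),
    error = function(e) NULL)
  span <- diff(range(fw))
  ok <- !is.null(fit) && fit$convergence == 0 && fit$par[["sigma"]] != 0 &&
    abs(fit$par[["cf"]] - f[peak_index]) <= span / 2 &&
    abs(fit$par[["sigma"]]) <= span  # reject fits that escape their window
  if (ok) {
    co <- fit$par
    sigma <- abs(co[["sigma"]])
    out <- list(cf = co[["cf"]], amplitude = co[["a"]], sigma = sigma,
                fwhm = 2 * sigma * sqrt(2 * log(2)),
                fw10m = 2 * sigma * sqrt(2 * log(10)),
                prominence = prominence, fitted = TRUE)
  } else {
    warnf("Gaussian fit did not converge at %.3f Hz; using empirical widths", f[peak_index])
    sigma <- half_width_bins * df_bin / sqrt(2 * log(2))
    out <- list(cf = f[peak_index], amplitude = x[peak_index], sigma = sigma,
                fwhm = 2 * sigma * sqrt(2 * log(2)),
                fw10m = 2 * sigma * sqrt(2 * log(10)),
                prominence = prominence, fitted = FALSE)
  }
  structure(out, class = "spectral_peak")
}

#' Preselect channels for cardiac-band fitting
#'
#' Channels must pass `cqi > cqi_thr`, `sci > sci_thr` and `psp > psp_thr`.
#' If no channel passes, the CQI threshold alone is relaxed in steps of
#' `relax_step` (floor 0) until at least one channel remains; the SCI and PSP
#' gates stay fixed.
#'
#' @param metrics data frame with per-channel columns `cqi`, `sci`, `psp`.
#' @param cqi_thr starting CQI threshold (default 0.9).
#' @param sci_thr fixed SCI gate (default 0.8).
#' @param psp_thr fixed PSP gate (default 0.1).
#' @param relax_step CQI relaxation step (default 0.05).
#' @return list with `channels` (1-based indices) and `cqi_threshold` used.
#' @export
select_best_channels <- function(metrics, cqi_thr = 0.9, sci_thr = 0.8,
                                 psp_thr = 0.1, relax_step = 0.05) {
  if (!nrow(metrics)) stopf("no channels")
  fixed <- metrics$sci > sci_thr & metrics$psp > psp_thr
  thr <- cqi_thr
  repeat {
    sel <- which(fixed & metrics$cqi > thr)
    if (length(sel)) return(list(channels = sel, cqi_threshold = thr))
    if (thr <= 0) stopf("no usable channel: preselection empty at CQI floor")
    thr <- max(0, round(thr - relax_step, 10))  # keep the schedule exact
  }
}

#' Median cardiac band across contributing channels
#'
#' `band = median(CF) +/- median(FW10M) / 2` over the fitted peaks of the
#' preselected channels, robust to single-channel outliers.
#'
#' @param peaks list of `spectral_peak` objects.
#' @param channels optional channel indices recorded in the result.
#' @return list of class `cardiac_band`: `cf_median`, `fw10m_median`, `low`,
#'   `high`, `channels`.
#' @export
subject_cardiac_band <- function(peaks, channels = seq_along(peaks)) {
  if (!length(peaks)) stopf("no peaks: cannot derive a cardiac band")
  cf <- stats::median(vapply(peaks, `[[`, numeric(1), "cf"))
  fw <- stats::median(vapply(peaks, `[[`, numeric(1), "fw10m"))
  structure(list(cf_median = cf, fw10m_median = fw,
                 low = cf - fw / 2, high = cf + fw / 2, channels = channels),
            class = "cardiac_band")
}

#' @export
print.cardiac_band <- function(x, ...) {
  cat(sprintf("<cardiac_band: CF %.3f Hz, FW10M %.3f Hz -> [%.3f, %.3f] Hz, %d channel(s)>\n",
              x$cf_median, x$fw10m_median, x$low, x$high, length(x$channels)))
  invisible(x)
}

#' Fit the subject-specific cardiac band of a recording
#'
#' Full composition over the oxyhemoglobin signals: index-based channel
#' preselection (CQI/SCI/PSP with CQI relaxation), Welch PSD, Savitzky-Golay
#' smoothing, aperiodic flattening, prominence-gated peak detection, Gaussian
#' fitting of each channel's cardiac candidate (the most prominent retained
#' peak within `hr_search_range`, ties broken towards lower frequency), and
#' the median band across channels.
#'
#' @param rec an `fnirs_recording`.
#' @param config a [spectral_fit_config()].
#' @param dpf DPF specification passed to [mbll_params()].
#' @return a `cardiac_band` (with fitted `peaks` attached as an attribute).
#' @export
fit_subject_band <- function(rec, config = spectral_fit_config(), dpf = 6) {
  stopifnot(inherits(rec, "fnirs_recording"))
  nch <- n_channels(rec)
  metrics <- do.call(rbind, lapply(seq_len(nch), function(ch) {
    m <- suppressWarnings(channel_quality_metrics(rec$intensity[, ch, 1],
                                                  rec$intensity[, ch, 2], rec$fs))
    data.frame(cqi = m$cqi, sci = m$sci, psp = m$psp)
  }))
  sel <- select_best_channels(metrics, relax_step = config$cqi_relax_step)
  hb <- recording_hb(rec, dpf = dpf)
  peaks <- list(); used <- integer()
  for (ch in sel$channels) {
    psd <- welch_psd(hb$hbo[, ch], rec$fs, window_s = config$welch_window_s,
                     average = config$psd_average %||% "mean")
    psd <- smooth_psd(psd, config$sg_frame_bins)
    flat <- flatten_spectrum(psd, config$fit_range)
    pk <- detect_peaks(flat, config$min_prominence_db)
    pk <- pk[pk$freq >= config$hr_search_range[1] &
               pk$freq <= config$hr_search_range[2], , drop = FALSE]
    if (!nrow(pk)) next
    pk <- pk[order(-pk$prominence, pk$freq), , drop = FALSE]
    fitted_pk <- fit_gaussian_peak(flat, pk$index[1], pk$prominence[1])
    if (fitted_pk$cf < config$hr_search_range[1] ||
          fitted_pk$cf > config$hr_search_range[2]) next
    peaks[[length(peaks) + 1]] <- fitted_pk
    used <- c(used, ch)
  }
  if (!length(peaks)) stopf("no usable channel: no cardiac peak found in preselected channels")
  band <- subject_cardiac_band(peaks, used)
  nyq <- rec$fs / 2
  if (band$low <= 0 || band$high >= nyq) {
    warnf("cardiac band [%.3f, %.3f] clipped to (0, Nyquist)", band$low, band$high)
    band$low <- max(band$low, 0.05)
    band$high <- min(band$high, 0.95 * nyq)
  }
  attr(band, "peaks") <- peaks
  attr(band, "cqi_threshold") <- sel$cqi_threshold
  band
}
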