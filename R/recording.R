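# Recording container and segment bookkeeping.

#' Construct an fNIRS recording
#'
#' The central container of the package: a dual-wavelength raw light-intensity
#' recording for one subject. Intensities are stored as a `time x channel x 2`
#' array (wavelength order follows `wavelengths`). Sample indices are 0-based
#' and half-open throughout the package.
#'
#' @param intensity numeric array `[time, channel, 2]`, strictly positive
#'   light intensity in arbitrary units.
#' @param fs sampling rate in Hz (> 0).
#' @param subject_id subject identifier string.
#' @param wavelengths two wavelengths in nm (default 760, 850 nm).
#' @param montage data frame with one row per channel: `source`, `detector`,
#'   `separation_mm`, `is_short`. A default 30 mm long-channel montage is
#'   synthesised when omitted.
#' @param age subject age in years, or `NULL` when unknown.
#' @param events optional numeric vector of event times (s).
#' @return object of class `fnirs_recording`.
#' @export
recording <- function(intensity, fs, subject_id = "S01",
                      wavelengths = c(760, 850), montage = NULL,
                      age = NULL, events = NULL) {
  if (length(dim(intensity)) != 3 || dim(intensity)[3] != 2) {
    stop_format("intensity must be a [time x channel x 2] array (got dims %s)",
                paste(dim(intensity), collapse = "x"))
  }
  if (any(!is.finite(intensity))) {
    bad <- which(!is.finite(intensity), arr.ind = TRUE)[1, ]
    stop_format("non-finite intensity at sample %d, channel %d, wavelength %d",
                bad[1], bad[2], bad[3])
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stopf("fs must be a positive scalar")
  if (length(wavelengths) != 2) stop_format("exactly 2 wavelengths required")
  n_ch <- dim(intensity)[2]
  if (is.null(montage)) {
    montage <- data.frame(source = seq_len(n_ch), detector = seq_len(n_ch),
                          separation_mm = 30, is_short = FALSE)
  }
  if (nrow(montage) != n_ch) {
    stop_format("montage has %d rows for %d channels", nrow(montage), n_ch)
  }
  if (!is.null(age) && (!is.numeric(age) || age <= 0 || age >= 120)) {
    stopf("age must be in (0, 120) years")
  }
  structure(list(subject_id = subject_id, intensity = intensity, fs = fs,
                 wavelengths = wavelengths, montage = montage, age = age,
                 events = events),
            class = "fnirs_recording")
}

#' @export
print.fnirs_recording <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<fnirs_recording %s: %d samples x %d channels x 2 wavelengths (%g/%g nm), fs %g Hz, %.1f s%s>\n",
              x$subject_id, d[1], d[2], x$wavelengths[1], x$wavelengths[2],
              x$fs, d[1] / x$fs,
              if (is.null(x$age)) "" else sprintf(", age %g", x$age)))
  invisible(x)
}

n_channels <- function(rec) dim(rec$intensity)[2]
n_samples <- function(rec) dim(rec$intensity)[1]

#' Split every channel of a recording into equal segments
#'
#' Each channel is divided into `n_segments` equal, contiguous,
#' non-overlapping segments. Remainder samples that do not fill a whole
#' segment are dropped from the end of the recording. Intervals are 0-based
#' and half-open.
#'
#' @param rec an `fnirs_recording`.
#' @param n_segments number of segments per channel (>= 1).
#' @return data frame of segment references: `subject_id`, `channel_index`
#'   (0-based), `segment_index` (0-based), `start_sample`, `end_sample`.
#' @export
segment_channels <- function(rec, n_segments = 5) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (n_segments < 1) stopf("n_segments must be >= 1")
  n <- n_samples(rec)
  seg_len <- floor(n / n_segments)
  if (seg_len < 1) stopf("recording too short (%d samples) for %d segments", n, n_segments)
  nc <- n_channels(rec)
  ch <- rep(seq_len(nc) - 1L, each = n_segments)
  sg <- rep(seq_len(n_segments) - 1L, times = nc)
  data.frame(subject_id = rec$subject_id,
             channel_index = ch,
             segment_index = sg,
             start_sample = sg * seg_len,
             end_sample = (sg + 1) * seg_len)
}

segment_slice <- function(rec, channel_index, start_sample, end_sample, wavelength = NULL) {
  idx <- (start_sample + 1):end_sample
  if (is.null(wavelength)) {
    rec$intensity[idx, channel_index + 1, , drop = TRUE]
  } else {
    rec$intensity[idx, channel_index + 1, wavelength]
  }
}
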