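# End-to-end composition helpers shared by the CLI, tests and acceptance
# script: recording -> cardiac band -> standardized scalogram images.

#' Standardized scalogram images for every segment of a recording
#'
#' Full pipeline for one subject: hemoglobin conversion, cardiac-band fit,
#' per-channel band filtering, Morlet CWT per segment, channel-pooled
#' normalization and row-30 standardization.
#'
#' @param rec an `fnirs_recording`.
#' @param n_segments segments per channel.
#' @param spectral a [spectral_fit_config()].
#' @param size output image side (default 224).
#' @param target_row cardiac anchor row (default 30).
#' @param dpf DPF specification (see [mbll_params()]).
#' @return list with `band` (the fitted `cardiac_band`), `segments` (the
#'   segment reference data frame) and `images` (list of `fnirs_std_image`
#'   aligned with `segments` rows).
#' @export
recording_scalograms <- function(rec, n_segments = 5,
                                 spectral = spectral_fit_config(),
                                 size = 224, target_row = 30, dpf = 6) {
  band <- fit_subject_band(rec, spectral, dpf = dpf)
  segs <- segment_channels(rec, n_segments)
  hb <- recording_hb(rec, dpf = dpf)
  images <- vector("list", nrow(segs))
  for (ch in sort(unique(segs$channel_index))) {
    rows <- which(segs$channel_index == ch)
    imgs <- channel_scalograms(hb$hbo[, ch + 1], rec$fs, band,
                               segs[rows, , drop = FALSE],
                               size = size, target_row = target_row)
    images[rows] <- imgs
  }
  list(band = band, segments = segs, images = images)
}

#' Build a labeled sample set from recordings and a label table
#'
#' Runs [recording_scalograms()] per subject and joins the ground-truth
#' labels, producing the image list + metadata frame consumed by
#' [train_classifier()] and [predict_quality()]. Subjects whose cardiac band
#' cannot be fitted are dropped with a warning.
#'
#' @param recordings list of `fnirs_recording`s.
#' @param labels label data frame (`subject_id`, `channel_index`,
#'   `segment_index`, `label`).
#' @param n_segments segments per channel.
#' @param size image side.
#' @param ... passed to [recording_scalograms()].
#' @return list with `images` (list of `[size, size, 3]` pixel arrays) and
#'   `meta` (data frame with subject/channel/segment and label).
#' @export
build_samples <- function(recordings, labels, n_segments = 5, size = 224, ...) {
  images <- list(); meta <- list()
  for (rec in recordings) {
    res <- tryCatch(recording_scalograms(rec, n_segments, size = size, ...),
                    error = function(e) {
                      warnf("subject %s skipped: %s", rec$subject_id, conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    m <- res$segments
    key <- paste(m$subject_id, m$channel_index, m$segment_index)
    lkey <- paste(labels$subject_id, labels$channel_index, labels$segment_index)
    m$label <- labels$label[match(key, lkey)]
    if (anyNA(m$label)) stopf("labels missing for some segments of %s", rec$subject_id)
    images <- c(images, lapply(res$images, `[[`, "pixels"))
    meta[[length(meta) + 1]] <- m
  }
  if (!length(images)) stopf("no usable subjects")
  list(images = images, meta = do.call(rbind, meta))
}
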