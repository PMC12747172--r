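# Quality reports and label files.

#' Build a quality report from per-segment predictions
#'
#' Aggregates segment-level predictions to channel-level quality percentages
#' (percentage of segments predicted high-quality, exact rational count before
#' rounding happens only at print/write time).
#'
#' @param segments data frame with `subject_id`, `channel_index`,
#'   `segment_index`, `label` ("high"/"low") and `p_low` (probability of low
#'   quality).
#' @return object of class `fnirsqc_quality_report` with elements `segments`
#'   and `channels`.
#' @export
quality_report <- function(segments) {
  req <- c("subject_id", "channel_index", "segment_index", "label", "p_low")
  if (!all(req %in% names(segments))) {
    stopf("segments must have columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(segments) && !all(segments$label %in% c("high", "low"))) {
    stopf("labels must be 'high' or 'low'")
  }
  segments <- segments[order(segments$subject_id, segments$channel_index,
                             segments$segment_index), req]
  rownames(segments) <- NULL
  if (nrow(segments)) {
    key <- interaction(segments$subject_id, segments$channel_index, drop = TRUE)
    n_high <- tapply(segments$label == "high", key, sum)
    n_tot <- tapply(segments$label, key, length)
    first <- !duplicated(key)
    channels <- data.frame(subject_id = segments$subject_id[first],
                           channel_index = segments$channel_index[first],
                           quality_pct = 100 * as.numeric(n_high[levels(key)][match(key[first], levels(key))]) /
                             as.numeric(n_tot[levels(key)][match(key[first], levels(key))]))
    channels <- channels[order(channels$subject_id, channels$channel_index), ]
    rownames(channels) <- NULL
  } else {
    channels <- data.frame(subject_id = character(), channel_index = integer(),
                           quality_pct = numeric())
  }
  structure(list(segments = segments, channels = channels),
            class = "fnirsqc_quality_report")
}

#' Write a quality report to CSV or JSON
#'
#' CSV layout: segment rows first (`row_type = "segment"`), then channel
#' summary rows (`row_type = "channel"`), in deterministic
#' subject/channel/segment order; both formats round-trip through
#' [read_quality_report()].
#'
#' @param report a `fnirsqc_quality_report`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @export
write_quality_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "fnirsqc_quality_report"))
  if (format == "json") {
    jsonlite::write_json(list(segments = report$segments, channels = report$channels),
                         path, digits = NA, auto_unbox = TRUE)
  } else {
    seg <- report$segments
    segdf <- data.frame(row_type = rep("segment", nrow(seg)), seg,
                        quality_pct = rep(NA_real_, nrow(seg)))
    ch <- report$channels
    chdf <- data.frame(row_type = rep("channel", nrow(ch)),
                       subject_id = ch$subject_id, channel_index = ch$channel_index,
                       segment_index = rep(NA_integer_, nrow(ch)),
                       label = rep(NA_character_, nrow(ch)),
                       p_low = rep(NA_real_, nrow(ch)),
                       quality_pct = ch$quality_pct)
    utils::write.csv(rbind(segdf, chdf), path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Read a quality report written by [write_quality_report()]
#'
#' @param path file path; format inferred from the extension.
#' @return a `fnirsqc_quality_report`.
#' @export
read_quality_report <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    seg <- as.data.frame(obj$segments)
    if (!nrow(seg)) {
      seg <- data.frame(subject_id = character(), channel_index = integer(),
                        segment_index = integer(), label = character(),
                        p_low = numeric())
    }
    return(quality_report(seg))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  seg <- df[df$row_type == "segment",
            c("subject_id", "channel_index", "segment_index", "label", "p_low")]
  rownames(seg) <- NULL
  quality_report(seg)
}

#' Write segment labels to CSV
#'
#' The label-file contract replacing interactive annotation: columns
#' `subject_id`, `channel_index`, `segment_index`, `label` with
#' `label %in% c("high", "low")`, written in deterministic order.
#'
#' @param labels data frame with the four columns above.
#' @param path output CSV path.
#' @export
write_labels <- function(labels, path) {
  req <- c("subject_id", "channel_index", "segment_index", "label")
  stopifnot(all(req %in% names(labels)), all(labels$label %in% c("high", "low")))
  labels <- labels[order(labels$subject_id, labels$channel_index,
                         labels$segment_index), req]
  utils::write.csv(labels, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a segment label CSV
#' @param path CSV path written by [write_labels()] or hand-edited.
#' @return data frame with `subject_id`, `channel_index`, `segment_index`, `label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "channel_index", "segment_index", "label")
  if (!all(req %in% names(df))) stop_format("label file %s lacks required columns", path)
  if (!all(df$label %in% c("high", "low"))) stop_format("labels must be 'high'/'low'")
  df[req]
}
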