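# Homer-style .nirs/.mat support through a small Python (scipy.io) bridge;
# no MATLAB-file reader exists in the R dependency set. The bridge converts
# the MAT structure to JSON and back.

python_bin <- function() {
  p <- getOption("fnirsqc.python", "")
  if (!nzchar(p)) p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stopf("no python interpreter found (needed for .nirs/.mat support)")
  unname(p)
}

mat_bridge <- function(mode, input, output) {
  script <- system.file("python", "mat_bridge.py", package = "fnirsqc")
  if (!nzchar(script)) stopf("mat_bridge.py not found in installed package")
  status <- suppressWarnings(
    system2(python_bin(), c(shQuote(script), mode, shQuote(input), shQuote(output)),
            stdout = TRUE, stderr = TRUE))
  code <- attr(status, "status") %||% 0
  if (code != 0) {
    err <- tryCatch(jsonlite::read_json(output)$error, error = function(e) NULL)
    stop_format("MATLAB bridge failed: %s",
                err %||% paste(status, collapse = "; "))
  }
  invisible(NULL)
}

#' Read a Homer-style .nirs/.mat recording
#'
#' Mandatory fields: `d` (time x measurement matrix) and `SD` (probe struct
#' with `MeasList`). `d` is interpreted as raw light intensity (the .nirs
#' convention; the processing pipeline starts from raw intensity). Measurement
#' columns are paired into channels via the `MeasList` wavelength index.
#' Optional fields `t` (time vector, used to derive `fs` when not supplied),
#' `s`, `aux` and `age` are honoured; `s`/`aux` are ignored beyond events.
#'
#' @param path `.nirs` or `.mat` file.
#' @param fs sampling rate in Hz; required when the file has no `t` vector.
#' @param subject_id subject identifier (default: file name without extension).
#' @return an `fnirs_recording`.
#' @export
read_nirs_mat <- function(path, fs = NULL, subject_id = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  mat_bridge("read", path, tmp)
  obj <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  if (!is.null(obj$error)) stop_format("MATLAB bridge: %s", obj$error)
  d <- as.matrix(obj$d)
  ml <- as.matrix(obj$meas_list)  # columns: source, detector, ?, wavelengthIndex
  if (nrow(ml) != ncol(d)) {
    stop_format("d has %d columns but MeasList has %d rows", ncol(d), nrow(ml))
  }
  if (is.null(fs)) {
    if (is.null(obj$t) || length(obj$t) < 2) {
      stopf("fs not supplied and file has no usable time vector")
    }
    fs <- 1 / stats::median(diff(obj$t))
  }
  wl_idx <- ml[, 4]
  pairs <- unique(ml[, 1:2, drop = FALSE])
  nch <- nrow(pairs)
  intensity <- array(0, c(nrow(d), nch, 2))
  for (ch in seq_len(nch)) {
    for (wl in 1:2) {
      col <- which(ml[, 1] == pairs[ch, 1] & ml[, 2] == pairs[ch, 2] & wl_idx == wl)
      if (length(col) != 1) {
        stop_format("channel (source %d, detector %d) lacks wavelength index %d",
                    pairs[ch, 1], pairs[ch, 2], wl)
      }
      intensity[, ch, wl] <- d[, col]
    }
  }
  wavelengths <- if (!is.null(obj[["lambda"]])) as.numeric(obj[["lambda"]]) else c(760, 850)
  sep <- rep(30, nch)
  if (!is.null(obj$src_pos) && !is.null(obj$det_pos)) {
    sp <- as.matrix(obj$src_pos); dp <- as.matrix(obj$det_pos)
    if (max(pairs[, 1]) <= nrow(sp) && max(pairs[, 2]) <= nrow(dp)) {
      sep <- sqrt(rowSums((sp[pairs[, 1], , drop = FALSE] -
                             dp[pairs[, 2], , drop = FALSE])^2))
    }
  }
  age <- if (!is.null(obj$age)) as.numeric(obj$age)[1] else NULL
  events <- if (!is.null(obj$s)) which(obj$s != 0) / fs else NULL
  montage <- data.frame(source = pairs[, 1], detector = pairs[, 2],
                        separation_mm = sep, is_short = sep < 15)
  recording(intensity, fs,
            subject_id = subject_id %||% sub("\\.[^.]+$", "", basename(path)),
            wavelengths = wavelengths, montage = montage, age = age,
            events = events)
}

#' Write a recording as a Homer-style .nirs/.mat file
#'
#' Writes `d` (raw intensity, time x measurement), `SD` with `MeasList`,
#' `Lambda`, `SrcPos`/`DetPos` (mm, consistent with the montage separations),
#' plus `t` and, when known, `age`.
#'
#' @param rec an `fnirs_recording`.
#' @param path output `.nirs`/`.mat` path.
#' @return `path`, invisibly.
#' @export
write_nirs_mat <- function(rec, path) {
  stopifnot(inherits(rec, "fnirs_recording"))
  n <- n_samples(rec); nch <- n_channels(rec)
  d <- matrix(0, n, 2 * nch)
  ml <- matrix(0, 2 * nch, 4)
  for (wl in 1:2) {
    cols <- (wl - 1) * nch + seq_len(nch)
    d[, cols] <- rec$intensity[, , wl]
    ml[cols, ] <- cbind(rec$montage$source, rec$montage$detector, 1, wl)
  }
  n_src <- max(rec$montage$source); n_det <- max(rec$montage$detector)
  src_pos <- cbind(100 * seq_len(n_src), 0, 0)
  det_pos <- matrix(0, n_det, 3)
  for (ch in seq_len(nch)) {
    det_pos[rec$montage$detector[ch], ] <-
      c(src_pos[rec$montage$source[ch], 1] + rec$montage$separation_mm[ch], 0, 0)
  }
  obj <- list(d = d, meas_list = ml, "lambda" = as.numeric(rec$wavelengths),
              src_pos = src_pos, det_pos = det_pos,
              t = (seq_len(n) - 1) / rec$fs)
  if (!is.null(rec$age)) obj$age <- rec$age
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = FALSE)
  mat_bridge("write", tmp, path)
  invisible(path)
}
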