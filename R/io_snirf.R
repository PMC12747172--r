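# Minimal SNIRF (HDF5) dialect: continuous-wave intensity with
# dataTimeSeries + measurementList + probe geometry. Other SNIRF blocks are
# ignored on read (with a message). Backed by rhdf5.

#' Write a recording as a minimal SNIRF v1 file
#'
#' Writes the continuous-wave subset of SNIRF: `/formatVersion`,
#' `/nirs/data1/dataTimeSeries` (time x measurement), `/nirs/data1/time`,
#' one `measurementList<k>` group per measurement, probe wavelengths and 3D
#' optode positions (mm) consistent with the montage separations, and
#' metaDataTags with the subject id and (if known) age.
#'
#' @param rec an `fnirs_recording`.
#' @param path output `.snirf` path.
#' @return `path`, invisibly.
#' @export
write_snirf <- function(rec, path) {
  stopifnot(inherits(rec, "fnirs_recording"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write("1.0", path, "formatVersion")
  rhdf5::h5createGroup(path, "nirs")
  rhdf5::h5createGroup(path, "nirs/data1")

  n <- n_samples(rec); nch <- n_channels(rec)
  # measurement order: all channels at wavelength 1, then all at wavelength 2
  dts <- matrix(0, n, 2 * nch)
  for (wl in 1:2) dts[, (wl - 1) * nch + seq_len(nch)] <- rec$intensity[, , wl]
  # store transposed so external (C-order) readers see [time, measurement]
  rhdf5::h5write(t(dts), path, "nirs/data1/dataTimeSeries")
  rhdf5::h5write((seq_len(n) - 1) / rec$fs, path, "nirs/data1/time")
  for (k in seq_len(2 * nch)) {
    g <- sprintf("nirs/data1/measurementList%d", k)
    rhdf5::h5createGroup(path, g)
    ch <- (k - 1) %% nch + 1
    wl <- (k - 1) %/% nch + 1
    rhdf5::h5write(as.integer(rec$montage$source[ch]), path, paste0(g, "/sourceIndex"))
    rhdf5::h5write(as.integer(rec$montage$detector[ch]), path, paste0(g, "/detectorIndex"))
    rhdf5::h5write(as.integer(wl), path, paste0(g, "/wavelengthIndex"))
    rhdf5::h5write(1L, path, paste0(g, "/dataType"))
    rhdf5::h5write(1L, path, paste0(g, "/dataTypeIndex"))
  }
  rhdf5::h5createGroup(path, "nirs/probe")
  rhdf5::h5write(as.numeric(rec$wavelengths), path, "nirs/probe/wavelengths")
  n_src <- max(rec$montage$source); n_det <- max(rec$montage$detector)
  src_pos <- cbind(100 * seq_len(n_src), 0, 0)
  det_pos <- matrix(0, n_det, 3)
  for (ch in seq_len(nch)) {
    s <- rec$montage$source[ch]; d <- rec$montage$detector[ch]
    det_pos[d, ] <- c(src_pos[s, 1] + rec$montage$separation_mm[ch], 0, 0)
  }
  rhdf5::h5write(t(src_pos), path, "nirs/probe/sourcePos3D")
  rhdf5::h5write(t(det_pos), path, "nirs/probe/detectorPos3D")
  rhdf5::h5createGroup(path, "nirs/metaDataTags")
  rhdf5::h5write(rec$subject_id, path, "nirs/metaDataTags/SubjectID")
  rhdf5::h5write("mm", path, "nirs/metaDataTags/LengthUnit")
  rhdf5::h5write("s", path, "nirs/metaDataTags/TimeUnit")
  if (!is.null(rec$age)) rhdf5::h5write(as.numeric(rec$age), path, "nirs/metaDataTags/Age")
  invisible(path)
}

h5_has <- function(listing, name) any(listing == name)

#' Read a SNIRF file (minimal continuous-wave dialect)
#'
#' Requires `/nirs/data1/dataTimeSeries`, the `measurementList<k>` groups and
#' the probe geometry. Measurements are grouped into channels by
#' (source, detector); every channel must carry both wavelengths. The
#' sampling rate is derived from the time vector unless `fs` is supplied.
#' Unsupported SNIRF blocks (aux, stim, additional data blocks) are ignored
#' with a message.
#'
#' @param path `.snirf` file path.
#' @param fs optional sampling rate override (Hz).
#' @return an `fnirs_recording`.
#' @export
read_snirf <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  full <- file.path(ls$group, ls$name)
  full <- sub("^/", "", sub("^//", "/", full))
  root <- if (any(grepl("^nirs($|/)", full))) "nirs"
          else if (any(grepl("^nirs1($|/)", full))) "nirs1" else
            stop_format("missing mandatory SNIRF group: /nirs")
  need <- paste0(root, "/data1/dataTimeSeries")
  if (!h5_has(full, need)) stop_format("missing mandatory SNIRF path: /%s", need)

  extra <- grep(sprintf("^%s/(aux|stim)", root), full, value = TRUE)
  if (length(extra)) message("read_snirf: ignoring unsupported SNIRF blocks: ",
                             paste(unique(dirname(extra)), collapse = ", "))

  dts <- rhdf5::h5read(path, need)
  # file stores [time, measurement] in C order -> R sees the transpose
  dts <- t(dts)
  ml_names <- grep(sprintf("^%s/data1/measurementList[0-9]+$", root), full, value = TRUE)
  if (!length(ml_names)) stop_format("missing mandatory SNIRF path: /%s/data1/measurementList*", root)
  k <- as.integer(sub(".*measurementList", "", ml_names))
  ml_names <- ml_names[order(k)]
  ml <- do.call(rbind, lapply(ml_names, function(g) {
    data.frame(source = as.integer(rhdf5::h5read(path, paste0(g, "/sourceIndex"))),
               detector = as.integer(rhdf5::h5read(path, paste0(g, "/detectorIndex"))),
               wavelength = as.integer(rhdf5::h5read(path, paste0(g, "/wavelengthIndex"))))
  }))
  if (nrow(ml) != ncol(dts)) {
    stop_format("dataTimeSeries has %d measurements but %d measurementList entries",
                ncol(dts), nrow(ml))
  }
  if (is.null(fs)) {
    tv <- as.numeric(rhdf5::h5read(path, paste0(root, "/data1/time")))
    fs <- if (length(tv) == 2) 1 / tv[2] else 1 / stats::median(diff(tv))
  }
  wavelengths <- as.numeric(rhdf5::h5read(path, paste0(root, "/probe/wavelengths")))
  if (length(wavelengths) != 2) stop_format("expected exactly 2 probe wavelengths")

  pairs <- unique(ml[c("source", "detector")])
  nch <- nrow(pairs)
  intensity <- array(0, c(nrow(dts), nch, 2))
  for (ch in seq_len(nch)) {
    for (wl in 1:2) {
      col <- which(ml$source == pairs$source[ch] & ml$detector == pairs$detector[ch] &
                     ml$wavelength == wl)
      if (length(col) != 1) {
        stop_format("channel (source %d, detector %d) lacks wavelength %d",
                    pairs$source[ch], pairs$detector[ch], wl)
      }
      intensity[, ch, wl] <- dts[, col]
    }
  }
  sep <- rep(30, nch)
  if (h5_has(full, paste0(root, "/probe/sourcePos3D"))) {
    sp <- t(rhdf5::h5read(path, paste0(root, "/probe/sourcePos3D")))
    dp <- t(rhdf5::h5read(path, paste0(root, "/probe/detectorPos3D")))
    sep <- sqrt(rowSums((sp[pairs$source, , drop = FALSE] -
                           dp[pairs$detector, , drop = FALSE])^2))
  }
  subject_id <- "S01"; age <- NULL
  if (h5_has(full, paste0(root, "/metaDataTags/SubjectID"))) {
    subject_id <- as.character(rhdf5::h5read(path, paste0(root, "/metaDataTags/SubjectID")))
  }
  if (h5_has(full, paste0(root, "/metaDataTags/Age"))) {
    age <- as.numeric(rhdf5::h5read(path, paste0(root, "/metaDataTags/Age")))
  }
  montage <- data.frame(source = pairs$source, detector = pairs$detector,
                        separation_mm = sep, is_short = sep < 15)
  recording(intensity, fs, subject_id = subject_id, wavelengths = wavelengths,
            montage = montage, age = age)
}
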