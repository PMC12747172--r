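# Seeded synthetic dual-wavelength fNIRS generator with ground-truth
# per-segment quality labels. The forward model inverts the package's own
# preprocessing: hemoglobin dynamics -> modified Beer-Lambert OD -> intensity,
# plus sensor noise and three low-quality modes (coupling loss, motion bursts,
# detector saturation).

#' Configuration of the synthetic recording generator
#'
#' Defaults describe a plausible adult resting-state recording: heart rate
#' uniform in 0.83-1.5 Hz (50-90 bpm), per-channel cardiac oxyhemoglobin
#' amplitude lognormal around 0.2 uM with 20% slow modulation and a 20%
#' second harmonic, Mayer waves near 0.1 Hz, respiration near 0.25 Hz, a 1/f
#' drift, and relative sensor noise of 3e-4 per wavelength. Low-quality
#' segments are drawn at `low_fraction` and realised as coupling loss
#' (uncorrelated optical noise, no cardiac signal), motion bursts (correlated
#' broadband excursions masking more than half of the segment) or detector
#' saturation (clipped constant intensity). High-quality segments may carry
#' minor (sub-50% coverage) motion artifacts at `minor_motion_rate`, the
#' realistic nuisance that makes fixed-threshold indices misfire.
#'
#' @param n_subjects number of subjects.
#' @param n_channels channels per subject.
#' @param duration_s recording duration (s).
#' @param fs sampling rate (Hz).
#' @param n_segments segments per channel.
#' @param hr_range heart-rate range (Hz) sampled uniformly per subject.
#' @param cardiac_amp_um median cardiac HbO amplitude (uM).
#' @param cardiac_amp_sdlog lognormal spread of the per-channel amplitude.
#' @param mayer_freq,mayer_amp Mayer-wave frequency (Hz) and amplitude (uM).
#' @param resp_freq,resp_amp respiration frequency (Hz) and amplitude (uM).
#' @param drift_alpha,drift_sd 1/f^alpha drift exponent and sd (uM).
#' @param noise_sd relative sensor noise sd per wavelength.
#' @param low_fraction probability a segment is low-quality.
#' @param mode_weights named weights for `coupling_loss`, `motion_burst`,
#'   `saturation` (must sum to 1).
#' @param minor_motion_rate probability of a minor artifact in a high segment.
#' @param hbr_ratio deoxy/oxy anticorrelation ratio (default -0.3).
#' @param hbr_noise_sd sd (uM) of the independent white noise added to HbR.
#' @param separation_mm source-detector separation (mm).
#' @param i0 baseline intensity (a.u.).
#' @param age subject age (years) or NULL.
#' @param seed base seed; every subject derives its own stream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10, n_channels = 8, duration_s = 300,
                       fs = 7.812, n_segments = 5, hr_range = c(0.83, 1.5),
                       cardiac_amp_um = 0.2, cardiac_amp_sdlog = 0.35,
                       mayer_freq = 0.1, mayer_amp = 0.1,
                       resp_freq = 0.25, resp_amp = 0.08,
                       drift_alpha = 2, drift_sd = 0.5,
                       noise_sd = 1e-4, low_fraction = 0.3,
                       mode_weights = c(coupling_loss = 0.4, motion_burst = 0.4,
                                        saturation = 0.2),
                       minor_motion_rate = 0.15, hbr_ratio = -0.3, hbr_noise_sd = 0.005,
                       separation_mm = 30, i0 = 1, age = NULL, seed = 1) {
  if (any(c(hr_range, mayer_freq, resp_freq) >= fs / 2)) {
    stopf("all physiological rates must be below Nyquist (%g Hz)", fs / 2)
  }
  if (low_fraction < 0 || low_fraction > 1) stopf("low_fraction must be in [0, 1]")
  if (abs(sum(mode_weights) - 1) > 1e-9 || any(mode_weights < 0)) {
    stopf("mode_weights must be nonnegative and sum to 1")
  }
  if (!all(c("coupling_loss", "motion_burst", "saturation") %in% names(mode_weights))) {
    stopf("mode_weights must name coupling_loss, motion_burst, saturation")
  }
  structure(as.list(environment()), class = "sim_config")
}

one_over_f <- function(n, alpha, sd_target) {
  # spectrally shaped Gaussian noise, mean 0, sd = sd_target
  white <- stats::rnorm(n)
  xf <- stats::fft(white)
  f <- c(1, seq_len(n - 1))  # avoid division by zero at DC
  f <- pmin(f, n - f + 1)
  shape <- f^(-alpha / 2)
  shape[1] <- 0
  x <- Re(stats::fft(xf * shape, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd_target
}

motion_artifact <- function(n_seg, coverage, fs) {
  # correlated broadband excursion (random walk + spikes) over `coverage`
  # of the segment, returned as an OD time course (same for both wavelengths
  # up to a wavelength scale factor applied by the caller)
  art <- numeric(n_seg)
  n_burst <- sample(1:3, 1)
  span_total <- round(coverage * n_seg)
  lens <- diff(round(seq(0, span_total, length.out = n_burst + 1)))
  lens <- lens[lens > 3]
  if (!length(lens)) lens <- max(span_total, 4)
  starts <- sort(sample(seq_len(max(n_seg - max(lens), 1)), length(lens)))
  spans <- list()
  for (j in seq_along(lens)) {
    s0 <- starts[j]; s1 <- min(s0 + lens[j] - 1, n_seg)
    rw <- cumsum(stats::rnorm(s1 - s0 + 1))
    rw <- rw / max(abs(rw), 1e-12) * stats::runif(1, 0.1, 0.4)
    # taper so the excursion starts/ends near zero (optode shift + recovery)
    tap <- sin(pi * seq(0, 1, length.out = length(rw)))
    art[s0:s1] <- art[s0:s1] + rw * tap
    # superimposed fast spikes
    n_spk <- max(1, round(length(rw) / fs / 2))
    at <- sample(seq_along(rw), min(n_spk, length(rw)))
    art[s0 + at - 1] <- art[s0 + at - 1] + stats::rnorm(length(at), 0, 0.15)
    spans[[j]] <- c(s0, s1)
  }
  list(od = art, spans = spans)
}

#' Simulate one subject's recording with ground truth
#'
#' @param cfg a [sim_config()].
#' @param subject_index 1-based subject number (drives the seed stream and the
#'   subject id `S<index>`).
#' @return list with `recording` (an `fnirs_recording`), `hr` (true heart
#'   rate, Hz), `segments` (ground-truth data frame: `subject_id`,
#'   `channel_index`, `segment_index`, `label`, `mode`, `coverage`).
#' @export
simulate_recording <- function(cfg, subject_index = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(cfg$seed, subject_index))

  n <- floor(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  seg_len <- floor(n / cfg$n_segments)
  hr <- stats::runif(1, cfg$hr_range[1], cfg$hr_range[2])
  params <- mbll_params(separation_mm = cfg$separation_mm)

  intensity <- array(0, c(n, cfg$n_channels, 2))
  ann <- vector("list", cfg$n_channels)
  subject_id <- sprintf("S%02d", subject_index)

  for (ch in seq_len(cfg$n_channels)) {
    amp <- stats::rlnorm(1, log(cfg$cardiac_amp_um), cfg$cardiac_amp_sdlog)
    ph <- stats::runif(4, 0, 2 * pi)
    modul <- 1 + 0.2 * sin(2 * pi * 0.03 * t + ph[1])
    cardiac <- amp * modul * sin(2 * pi * hr * t + ph[2]) +
      0.2 * amp * sin(2 * pi * 2 * hr * t + ph[3])
    hbo <- cardiac +
      cfg$mayer_amp * sin(2 * pi * cfg$mayer_freq * t + ph[4]) +
      cfg$resp_amp * sin(2 * pi * cfg$resp_freq * t + stats::runif(1, 0, 2 * pi)) +
      one_over_f(n, cfg$drift_alpha, cfg$drift_sd)
    hbr <- cfg$hbr_ratio * hbo + stats::rnorm(n, 0, cfg$hbr_noise_sd)
    od <- hb_to_od(cbind(hbo), cbind(hbr), params)[, 1, ]

    seg_label <- character(cfg$n_segments)
    seg_mode <- character(cfg$n_segments)
    seg_cov <- numeric(cfg$n_segments)
    saturated <- logical(n)
    for (sg in seq_len(cfg$n_segments)) {
      idx <- ((sg - 1) * seg_len + 1):(sg * seg_len)
      is_low <- stats::runif(1) < cfg$low_fraction
      if (is_low) {
        mode <- sample(names(cfg$mode_weights), 1, prob = cfg$mode_weights)
        if (mode == "coupling_loss") {
          # no shared hemodynamics; large uncorrelated optical noise
          od[idx, 1] <- stats::rnorm(length(idx), 0, 0.05)
          od[idx, 2] <- stats::rnorm(length(idx), 0, 0.05)
          seg_cov[sg] <- 1
        } else if (mode == "motion_burst") {
          cov <- stats::runif(1, 0.55, 0.9)
          art <- motion_artifact(length(idx), cov, cfg$fs)
          od[idx, 1] <- od[idx, 1] + art$od
          od[idx, 2] <- od[idx, 2] + 1.2 * art$od
          seg_cov[sg] <- cov
        } else { # saturation
          saturated[idx] <- TRUE
          seg_cov[sg] <- 1
        }
        seg_label[sg] <- "low"; seg_mode[sg] <- mode
      } else {
        seg_label[sg] <- "high"; seg_mode[sg] <- "clean"
        if (stats::runif(1) < cfg$minor_motion_rate) {
          cov <- stats::runif(1, 0.1, 0.4)
          art <- motion_artifact(length(idx), cov, cfg$fs)
          od[idx, 1] <- od[idx, 1] + art$od
          od[idx, 2] <- od[idx, 2] + 1.2 * art$od
          seg_mode[sg] <- "minor_motion"
          seg_cov[sg] <- cov
        }
      }
    }
    ii <- cfg$i0 * exp(-od) +
      matrix(stats::rnorm(2 * n, 0, cfg$noise_sd * cfg$i0), n, 2)
    # saturated samples: detector pinned at a constant reading
    ii[saturated, ] <- cfg$i0
    intensity[, ch, ] <- pmax(ii, 1e-6 * cfg$i0)

    ann[[ch]] <- data.frame(subject_id = subject_id,
                            channel_index = ch - 1L,
                            segment_index = seq_len(cfg$n_segments) - 1L,
                            label = seg_label, mode = seg_mode,
                            coverage = seg_cov)
  }
  montage <- data.frame(source = seq_len(cfg$n_channels),
                        detector = seq_len(cfg$n_channels),
                        separation_mm = cfg$separation_mm, is_short = FALSE)
  rec <- recording(intensity, cfg$fs, subject_id = subject_id,
                   montage = montage, age = cfg$age)
  list(recording = rec, hr = hr, segments = do.call(rbind, ann))
}

#' Simulate a labeled multi-subject dataset
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, each subject is written
#'   as `<subject>.snirf` and the labels as `labels.csv`.
#' @return list with `recordings` (list of `fnirs_recording`), `hr` (named
#'   vector of true heart rates), `labels` (data frame), and (when `dir` is
#'   given) `label_file`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  sims <- lapply(seq_len(cfg$n_subjects), function(i) simulate_recording(cfg, i))
  recs <- lapply(sims, `[[`, "recording")
  names(recs) <- vapply(recs, `[[`, character(1), "subject_id")
  hr <- vapply(sims, `[[`, numeric(1), "hr")
  names(hr) <- names(recs)
  labels <- do.call(rbind, lapply(sims, `[[`, "segments"))
  out <- list(recordings = recs, hr = hr,
              labels = labels[c("subject_id", "channel_index", "segment_index",
                                "label")],
              truth = labels)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (r in recs) write_snirf(r, file.path(dir, paste0(r$subject_id, ".snirf")))
    out$label_file <- write_labels(out$labels, file.path(dir, "labels.csv"))
  }
  out
}

# save/restore the global RNG state so simulators do not disturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
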