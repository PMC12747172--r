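# Shared fixtures, generated in code at test time.

# tiny simulated recording for IO / metric tests
tiny_sim <- function(n_channels = 3, duration_s = 30, fs = 7.812,
                     low_fraction = 0, seed = 42, ...) {
  cfg <- sim_config(n_subjects = 1, n_channels = n_channels,
                    duration_s = duration_s, fs = fs,
                    low_fraction = low_fraction, seed = seed, ...)
  simulate_recording(cfg, 1)
}

# an analytic dB spectrum on a regular grid, as an fnirs_psd
analytic_psd <- function(fun, fmin = 0.05, fmax = 3.9, df = 0.0167) {
  freqs <- seq(fmin, fmax, by = df)
  structure(list(freqs = freqs, power_db = fun(freqs), fs = 2 * fmax),
            class = "fnirs_psd")
}

# synthetic classifier images: class "low" has a fragmented band, class
# "high" a continuous bright band near the anchor row; tiny and fast
toy_image_set <- function(n_subjects = 8, per_subject = 6, size = 16, seed = 1) {
  set.seed(seed)
  images <- list(); meta <- list()
  for (s in seq_len(n_subjects)) {
    for (j in seq_len(per_subject)) {
      lab <- if (j %% 2 == 0) "low" else "high"
      img <- array(stats::runif(size * size * 3, 0, 0.05), c(size, size, 3))
      band <- 3:4
      if (lab == "high") {
        img[band, , 1] <- 0.9 + stats::rnorm(2 * size, 0, 0.02)
      } else {
        on <- sample(size, size %/% 3)
        img[band, on, 1] <- 0.9
      }
      images[[length(images) + 1]] <- img
      meta[[length(meta) + 1]] <- data.frame(
        subject_id = sprintf("T%02d", s), channel_index = 0L,
        segment_index = j - 1L, label = lab)
    }
  }
  list(images = images, meta = do.call(rbind, meta))
}

expect_no_subject_overlap <- function(a, b) {
  expect_length(intersect(a, b), 0)
}
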