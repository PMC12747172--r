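test_that("Welch PSD locates tones, flattens noise and floors silence", {
  fs <- 8
  t <- (0:(120 * fs - 1)) / fs
  p <- welch_psd(sin(2 * pi * 1.2 * t), fs, window_s = 60)
  expect_lt(abs(p$freqs[which.max(p$power_db)] - 1.2), fs / (60 * fs))

  set.seed(7)
  pn <- welch_psd(rnorm(1e5), fs, window_s = 60)
  expect_lt(sd(pn$power_db), 1.5)

  pz <- welch_psd(rep(0, 1000), fs, window_s = 60)
  expect_true(all(pz$power_db == -120))
  expect_error(welch_psd(rnorm(4), fs), "short")

  # median averaging agrees with mean on stationary noise (constant dB offset)
  pm <- welch_psd(rnorm(1e4), fs, 10, average = "median")
  expect_equal(length(pm$power_db), length(welch_psd(rnorm(1e4), fs, 10)$power_db))
})

test_that("smooth_psd reproduces cubic spectra and keeps peak location", {
  psd <- analytic_psd(function(f) 1 + 2 * f - 0.3 * f^2 + 0.05 * f^3)
  sm <- smooth_psd(psd, 11)
  expect_lt(max(abs(sm$power_db - psd$power_db)), 1e-9)

  set.seed(8)
  noisy <- analytic_psd(function(f) 6 * exp(-(f - 1.2)^2 / (2 * 0.15^2)))
  noisy$power_db <- noisy$power_db + rnorm(length(noisy$freqs), 0, 0.2)
  sm <- smooth_psd(noisy, 11)
  expect_lte(abs(which.max(sm$power_db) -
                   which.min(abs(noisy$freqs - 1.2))), 1)
  expect_error(smooth_psd(analytic_psd(function(f) f, fmax = 0.2), 31), "frame")
})

test_that("flatten_spectrum removes polynomial backgrounds exactly", {
  psd <- analytic_psd(function(f) 2 + 0.5 * f - 0.1 * f^2)
  fl <- flatten_spectrum(psd)
  expect_lt(max(abs(fl$power_db)), 1e-9)

  # cubic + Gaussian bump: residual peak at the bump
  psd2 <- analytic_psd(function(f) 5 - 2 * f + 0.2 * f^3 +
                         6 * exp(-(f - 1.2)^2 / (2 * 0.15^2)))
  fl2 <- flatten_spectrum(psd2)
  expect_lt(abs(fl2$freqs[which.max(fl2$power_db)] - 1.2), 0.1)
  expect_lt(abs(max(fl2$power_db) - 6), 1)

  # idempotence: refitting a cubic to the residual gives ~zero coefficients
  refit <- flatten_spectrum(fl2)
  expect_lt(max(abs(refit$power_db - fl2$power_db)), 1.5)  # bump perturbs mildly
  X <- outer(fl2$freqs, 0:3, `^`)
  beta <- qr.coef(qr(X), flatten_spectrum(psd)$power_db)
  expect_lt(max(abs(beta)), 1e-6)
})

test_that("1/f noise flattens to near zero on average", {
  set.seed(9)
  fs <- 8
  x <- fnirsqc:::one_over_f(2^15, 1, 1)
  psd <- welch_psd(x, fs, window_s = 120)
  fl <- flatten_spectrum(smooth_psd(psd, 11), c(0.05, 3.9))
  sel <- fl$freqs >= 0.05 & fl$freqs <= 3.9
  expect_lt(mean(abs(fl$power_db[sel])), 1)
})

test_that("detect_peaks applies the prominence gate", {
  flat0 <- analytic_psd(function(f) rep(0, length(f)))
  expect_equal(nrow(detect_peaks(flat0)), 0)

  one <- analytic_psd(function(f) 6 * exp(-(f - 1.2)^2 / (2 * 0.15^2)))
  pk <- detect_peaks(one, 0.5)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$freq - 1.2), 0.02)
  expect_equal(pk$prominence, 6, tolerance = 0.01)

  two <- analytic_psd(function(f) 6 * exp(-(f - 1.2)^2 / (2 * 0.15^2)) +
                        0.3 * exp(-(f - 2.5)^2 / (2 * 0.1^2)))
  expect_equal(nrow(detect_peaks(two, 0.5)), 1)
  expect_equal(nrow(detect_peaks(two, 0.2)), 2)
})

test_that("Gaussian peak fit recovers the closed-form widths", {
  g <- analytic_psd(function(f) 6 * exp(-(f - 1.2)^2 / (2 * 0.15^2)))
  pk <- detect_peaks(g, 0.5)
  fit <- fit_gaussian_peak(g, pk$index[1], pk$prominence[1])
  expect_true(fit$fitted)
  expect_equal(fit$cf, 1.2, tolerance = 1e-3)
  expect_equal(fit$fwhm, 2 * 0.15 * sqrt(2 * log(2)), tolerance = 1e-3)
  expect_equal(fit$fw10m, 2 * 0.15 * sqrt(2 * log(10)), tolerance = 1e-3)
  expect_equal(fit$fw10m / fit$fwhm, sqrt(log(10) / log(2)), tolerance = 1e-3)

  set.seed(10)
  gn <- g; gn$power_db <- gn$power_db + rnorm(length(g$freqs), 0, 0.2)
  pkn <- detect_peaks(gn, 0.5)
  pkn <- pkn[which.max(pkn$prominence), ]
  fitn <- fit_gaussian_peak(gn, pkn$index, pkn$prominence)
  expect_lt(abs(fitn$cf - 1.2), 0.02)
})

test_that("channel preselection relaxes only the CQI gate", {
  m <- data.frame(cqi = c(0.95, 0.5), sci = c(0.9, 0.9), psp = c(0.2, 0.2))
  sel <- select_best_channels(m)
  expect_equal(sel$channels, 1)
  expect_equal(sel$cqi_threshold, 0.9)

  m2 <- data.frame(cqi = rep(0.6, 4), sci = rep(0.85, 4), psp = rep(0.15, 4))
  sel2 <- select_best_channels(m2)
  expect_equal(sel2$channels, 1:4)
  expect_equal(sel2$cqi_threshold, 0.55, tolerance = 1e-9)

  m3 <- data.frame(cqi = rep(1, 3), sci = rep(0.1, 3), psp = rep(0.2, 3))
  expect_error(select_best_channels(m3), "no usable channel")
})

test_that("subject band is the median CF +/- median FW10M / 2", {
  mk <- function(cf, fw) structure(list(cf = cf, fw10m = fw, fwhm = fw / 1.82,
                                        sigma = 1, amplitude = 1,
                                        prominence = 1, fitted = TRUE),
                                   class = "spectral_peak")
  b1 <- subject_cardiac_band(list(mk(1.2, 0.4)))
  expect_equal(c(b1$low, b1$high), c(1.0, 1.4))

  b2 <- subject_cardiac_band(list(mk(1.1, 0.4), mk(1.2, 0.4), mk(1.3, 0.8)))
  expect_equal(c(b2$low, b2$high), c(1.0, 1.4))

  b3 <- subject_cardiac_band(list(mk(1.2, 0.4), mk(1.2, 0.4), mk(3.0, 0.4)))
  expect_equal(b3$cf_median, 1.2)
  expect_error(subject_cardiac_band(list()), "no peaks")
})

test_that("fit_subject_band recovers adult and infant heart rates", {
  cfg <- sim_config(n_subjects = 1, n_channels = 8, duration_s = 300, fs = 8,
                    hr_range = c(1.1, 1.1), low_fraction = 0, seed = 101)
  sim <- simulate_recording(cfg, 1)
  band <- suppressWarnings(fit_subject_band(sim$recording))
  expect_lte(abs(band$cf_median - 1.1), 0.05)
  expect_true(band$low < 1.1 && band$high > 1.1)

  cfg_inf <- sim_config(n_subjects = 1, n_channels = 8, duration_s = 300, fs = 8,
                        hr_range = c(2.4, 2.4), low_fraction = 0, seed = 102)
  sim_inf <- simulate_recording(cfg_inf, 1)
  band_inf <- suppressWarnings(fit_subject_band(sim_inf$recording))
  expect_lte(abs(band_inf$cf_median - 2.4), 0.05)

  cfg_bad <- sim_config(n_subjects = 1, n_channels = 4, duration_s = 200, fs = 8,
                        low_fraction = 1,
                        mode_weights = c(coupling_loss = 1, motion_burst = 0,
                                         saturation = 0), seed = 103)
  sim_bad <- simulate_recording(cfg_bad, 1)
  expect_error(suppressWarnings(fit_subject_band(sim_bad$recording)),
               "no usable channel")
})

test_that("median CF is insensitive to one corrupted channel", {
  cfg <- sim_config(n_subjects = 1, n_channels = 6, duration_s = 300, fs = 8,
                    hr_range = c(1.2, 1.2), low_fraction = 0,
                    minor_motion_rate = 0, seed = 104)
  sim <- simulate_recording(cfg, 1)
  rec <- sim$recording
  band0 <- suppressWarnings(fit_subject_band(rec))
  # replace one channel by coupling-loss style noise
  set.seed(1)
  rec$intensity[, 6, ] <- exp(-matrix(rnorm(2 * nrow(rec$intensity), 0, 0.05),
                                      ncol = 2))
  band1 <- suppressWarnings(fit_subject_band(rec))
  expect_lt(abs(band1$cf_median - band0$cf_median), 0.03)
})
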