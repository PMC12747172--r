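band_12 <- structure(list(cf_median = 1.2, fw10m_median = 0.4,
                          low = 1.0, high = 1.4, channels = 1),
                     class = "cardiac_band")

test_that("bandpass_cardiac keeps the cardiac tone and rejects harmonics", {
  fs <- 8; t <- (0:2399) / fs
  amp <- function(v) sqrt(2 * mean(v^2))
  y <- bandpass_cardiac(sin(2 * pi * 1.2 * t), fs, band_12)
  expect_gt(amp(y), 0.95)
  h <- bandpass_cardiac(sin(2 * pi * 3 * 1.4 * t), fs, band_12)
  expect_lt(20 * log10(amp(h) + 1e-15), -20)
  expect_equal(bandpass_cardiac(rep(0, 200), fs, band_12), rep(0, 200))
  bad <- band_12; bad$low <- 3.9; bad$high <- 4.5
  expect_error(bandpass_cardiac(rnorm(100), fs, bad), "Nyquist")
})

test_that("Morlet CWT ridges sit at the injected frequencies", {
  fs <- 8; t <- (0:2399) / fs
  sc <- cwt_morlet(sin(2 * pi * 1.2 * t), fs)
  mid <- 300:2100
  ridge <- sc$freqs[apply(sc$magnitude[, mid], 2, which.max)]
  # within half a voice (12 voices/octave)
  expect_true(all(abs(log2(ridge / 1.2)) <= 0.5 / 12 + 1e-9))

  z <- cwt_morlet(rep(0, 500), fs)
  expect_equal(max(z$magnitude), 0)

  two <- cwt_morlet(sin(2 * pi * 0.9 * t) + sin(2 * pi * 1.4 * t), fs)
  r09 <- which.min(abs(two$freqs - 0.9)); r14 <- which.min(abs(two$freqs - 1.4))
  on09 <- mean(two$magnitude[r09, mid] > 0.5)
  on14 <- mean(two$magnitude[r14, mid] > 0.5)
  expect_gt(on09, 0.95); expect_gt(on14, 0.95)
  expect_error(cwt_morlet(rnorm(100), fs, freqs = c(5, 4)), "Nyquist")
})

test_that("normalize_segments pools min-max across a channel's segments", {
  mk <- function(m) structure(list(magnitude = m, freqs = c(2, 1),
                                   times = seq_len(ncol(m))),
                              class = "fnirs_scalogram")
  one <- normalize_segments(list(mk(matrix(c(1, 2, 3, 5), 2))))
  expect_equal(range(one[[1]]$magnitude), c(0, 1))

  a <- mk(matrix(c(0, 1, 2, 4), 2))    # max 4
  b <- mk(matrix(c(0, 2, 4, 8), 2))    # max 8 (twice segment a's)
  nn <- normalize_segments(list(a, b))
  expect_equal(max(nn[[1]]$magnitude), 0.5)   # shared scale
  expect_equal(max(nn[[2]]$magnitude), 1)

  expect_warning(z <- normalize_segments(list(mk(matrix(0, 2, 2)))), "constant")
  expect_true(all(z[[1]]$magnitude == 0))

  # idempotence and order invariance
  twice <- normalize_segments(nn)
  expect_equal(twice, nn, tolerance = 1e-12)
  rev_in <- normalize_segments(list(b, a))
  expect_equal(rev_in[[2]]$magnitude, nn[[1]]$magnitude, tolerance = 1e-12)
})

test_that("jet colormap hits the documented breakpoints", {
  ends <- jet_rgb(c(0, 1))
  expect_equal(unname(ends[1, ]), c(0, 0, 0.5))
  expect_equal(unname(ends[2, ]), c(0.5, 0, 0))
  midv <- jet_rgb(0.5)
  expect_true(midv[1, "r"] < midv[1, "g"] && midv[1, "b"] < midv[1, "g"])
  # clipping
  expect_equal(jet_rgb(c(-1, 2)), jet_rgb(c(0, 1)))
})

test_that("align_and_resize standardizes shape and anchor row", {
  fs <- 8; t <- (0:1999) / fs
  x <- bandpass_cardiac(sin(2 * pi * 1.2 * t), fs, band_12)
  sc <- normalize_segments(list(cwt_morlet(x, fs)))[[1]]
  img <- align_and_resize(sc, band_12)
  expect_equal(dim(img$pixels), c(224, 224, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  ridge_rows <- apply(img$field, 2, which.max)
  keep <- apply(img$field, 2, max) > 0.1
  expect_equal(as.integer(names(which.max(table(ridge_rows[keep])))), 30)

  zero <- sc; zero$magnitude[] <- 0
  uz <- align_and_resize(zero, band_12)
  expect_true(all(abs(sweep(uz$pixels, 3, c(0, 0, 0.5))) < 1e-12))

  off <- band_12; off$cf_median <- 9
  expect_error(align_and_resize(sc, off), "outside")
})

test_that("time rescaling preserves the ridge column count", {
  fs <- 8; t1 <- (0:1599) / fs
  x1 <- bandpass_cardiac(sin(2 * pi * 1.2 * t1), fs, band_12)
  sc1 <- normalize_segments(list(cwt_morlet(x1, fs)))[[1]]
  i1 <- align_and_resize(sc1, band_12)
  t2 <- (0:2079) / fs   # 1.3x longer record of the same process
  x2 <- bandpass_cardiac(sin(2 * pi * 1.2 * t2), fs, band_12)
  sc2 <- normalize_segments(list(cwt_morlet(x2, fs)))[[1]]
  i2 <- align_and_resize(sc2, band_12)
  on1 <- sum(apply(i1$field, 2, max) > 0.5)
  on2 <- sum(apply(i2$field, 2, max) > 0.5)
  expect_lte(abs(on1 - on2), 2)
})
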