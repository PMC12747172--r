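test_that("SNIRF round trip preserves data, montage, metadata", {
  sim <- tiny_sim(n_channels = 2, duration_s = 13, fs = 7.812,
                  age = 34, seed = 7)
  rec <- sim$recording
  path <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(rec, path)
  r2 <- read_snirf(path)
  expect_equal(dim(r2$intensity), dim(rec$intensity))
  expect_equal(r2$intensity, rec$intensity, tolerance = 1e-12)
  expect_equal(r2$fs, 7.812, tolerance = 1e-9)
  expect_equal(r2$wavelengths, c(760, 850))
  expect_equal(r2$montage$separation_mm, rec$montage$separation_mm, tolerance = 1e-9)
  expect_equal(r2$age, 34)
  expect_equal(r2$subject_id, rec$subject_id)
})

test_that("SNIRF reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".snirf")
  rhdf5::h5createFile(path)
  rhdf5::h5write(1, path, "unrelated")
  rhdf5::h5closeAll()
  expect_error(read_snirf(path), "nirs", class = "fnirsqc_format_error")

  # a channel missing its second wavelength
  sim <- tiny_sim(n_channels = 2, duration_s = 10, seed = 8)
  path2 <- withr::local_tempfile(fileext = ".snirf")
  write_snirf(sim$recording, path2)
  rhdf5::h5delete(path2, "nirs/data1/measurementList4")
  rhdf5::h5closeAll()
  expect_error(read_snirf(path2), class = "fnirsqc_format_error")
})

test_that(".nirs/.mat round trip via the MATLAB bridge", {
  sim <- tiny_sim(n_channels = 28, duration_s = 12, fs = 8, age = 30, seed = 9)
  rec <- sim$recording
  path <- withr::local_tempfile(fileext = ".nirs")
  write_nirs_mat(rec, path)
  r2 <- read_nirs_mat(path)
  expect_equal(dim(r2$intensity)[2], 28)
  expect_equal(r2$intensity, rec$intensity, tolerance = 1e-9)
  expect_equal(r2$fs, 8, tolerance = 1e-9)
  expect_equal(r2$age, 30)
})

test_that(".mat reader errors without mandatory SD struct", {
  path <- withr::local_tempfile(fileext = ".mat")
  # write a MAT file with only d via the bridge's write? build one in python
  json <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(d = matrix(1, 4, 2)), json)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c("import scipy.io, json, sys, numpy as np",
               "obj = json.load(open(sys.argv[1]))",
               "scipy.io.savemat(sys.argv[2], {'d': np.asarray(obj['d'])})"),
             script)
  system2(Sys.which("python"), c(script, json, path))
  expect_error(read_nirs_mat(path, fs = 8), "SD", class = "fnirsqc_format_error")
})

test_that("segment_channels reproduces the printed dataset structure", {
  # one 1780 s, 28-channel recording at 7.812 Hz, reused for 40 subjects
  n <- floor(1780 * 7.812)
  rec <- recording(array(1, c(n, 28, 2)), fs = 7.812)
  total <- 0L
  for (i in 1:40) total <- total + nrow(segment_channels(rec, 5))
  expect_identical(total, 5600L)
  segs <- segment_channels(rec, 5)
  dur <- (segs$end_sample[1] - segs$start_sample[1]) / rec$fs
  expect_lt(abs(dur - 356), 0.5 / rec$fs * 5)  # within the remainder rounding
})

test_that("segment_channels partitions [0, n_seg * floor(T/n_seg)) exactly", {
  rec <- recording(array(1, c(103, 2, 2)), fs = 10)
  for (k in c(1, 2, 5, 7)) {
    segs <- segment_channels(rec, k)
    one <- segs[segs$channel_index == 0, ]
    expect_equal(one$start_sample, (seq_len(k) - 1) * floor(103 / k))
    expect_equal(one$end_sample, seq_len(k) * floor(103 / k))
    expect_equal(nrow(segs), 2 * k)
  }
  ten <- recording(array(1, c(10, 1, 2)), fs = 1)
  s1 <- segment_channels(ten, 1)
  expect_equal(c(s1$start_sample, s1$end_sample), c(0, 10))
  expect_error(segment_channels(rec, 200), "too short")
})

test_that("recording constructor enforces invariants", {
  expect_error(recording(array(1, c(10, 2, 3)), 8), class = "fnirsqc_format_error")
  bad <- array(1, c(10, 2, 2)); bad[3, 1, 2] <- NA
  expect_error(recording(bad, 8), "non-finite", class = "fnirsqc_format_error")
  expect_error(recording(array(1, c(10, 2, 2)), -1), "fs")
})

test_that("quality report round trips and channel percentages are exact", {
  seg <- data.frame(subject_id = "S01", channel_index = 0L,
                    segment_index = 0:4,
                    label = c("high", "high", "high", "low", "low"),
                    p_low = c(0.1, 0.2, 0.3, 0.8, 0.9))
  rep <- quality_report(seg)
  expect_equal(rep$channels$quality_pct, 60)

  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_quality_report(rep, path, fmt)
    r2 <- read_quality_report(path)
    expect_equal(r2$segments$label, rep$segments$label)
    expect_equal(r2$segments$p_low, rep$segments$p_low, tolerance = 1e-12)
    expect_equal(r2$channels, rep$channels, tolerance = 1e-12)
  }

  # empty report -> header-only file, still readable
  empty <- quality_report(seg[0, ])
  path <- withr::local_tempfile(fileext = ".csv")
  write_quality_report(empty, path, "csv")
  expect_equal(nrow(read_quality_report(path)$segments), 0)
})

test_that("channel percentage equals direct recount on random reports", {
  set.seed(11)
  for (rep_i in 1:5) {
    n_ch <- sample(2:5, 1); n_seg <- sample(3:8, 1)
    seg <- expand.grid(channel_index = seq_len(n_ch) - 1L,
                       segment_index = seq_len(n_seg) - 1L)
    seg$subject_id <- "X"
    seg$label <- sample(c("high", "low"), nrow(seg), replace = TRUE)
    seg$p_low <- stats::runif(nrow(seg))
    rep <- quality_report(seg)
    for (ch in seq_len(n_ch) - 1L) {
      direct <- 100 * sum(seg$label[seg$channel_index == ch] == "high") / n_seg
      expect_equal(rep$channels$quality_pct[rep$channels$channel_index == ch],
                   direct)
    }
  }
})

test_that("label files round trip", {
  lab <- data.frame(subject_id = c("S01", "S01", "S02"),
                    channel_index = c(0L, 1L, 0L),
                    segment_index = c(0L, 0L, 3L),
                    label = c("high", "low", "high"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_labels(lab, path)
  expect_equal(read_labels(path), lab)
  expect_error(write_labels(transform(lab, label = "bad"), path))
})
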