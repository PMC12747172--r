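test_that("confusion metrics match hand computation and printed F1 pairs", {
  truth <- c(rep("low", 5), rep("high", 5))
  pred <- c("low", "low", "low", "high", "high", "high", "high", "high", "high", "low")
  r <- confusion_metrics(truth, pred)
  expect_equal(c(r$tp, r$tn, r$fp, r$fn), c(3, 4, 1, 2))
  expect_equal(r$accuracy, 70)
  expect_equal(r$precision, 75)
  expect_equal(r$recall, 60)
  expect_equal(r$specificity, 80)
  expect_equal(r$f1, 2 * 75 * 60 / 135, tolerance = 1e-9)

  # published-table worked examples: F1 from (precision, recall)
  expect_equal(f1_from_pr(96.88, 23.66), 38.04, tolerance = 0.02)
  expect_equal(f1_from_pr(91.67, 93.27), 92.46, tolerance = 0.02)
  expect_equal(f1_from_pr(88.80, 86.90), 87.84, tolerance = 0.02)

  expect_error(confusion_metrics(truth, pred[1:5]), "length")
  w <- capture_warnings(r0 <- confusion_metrics(rep("high", 4), rep("high", 4)))
  expect_match(w, "undefined", all = FALSE)
  expect_true(is.nan(r0$recall))
})

test_that("perfect predictions and random tables obey identities", {
  set.seed(30)
  for (i in 1:10) {
    y <- sample(c("high", "low"), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    r <- confusion_metrics(y, y)
    expect_equal(r$accuracy, 100)
    expect_equal(r$f1, 100)
    p <- sample(c("high", "low"), 40, replace = TRUE)
    rp <- suppressWarnings(confusion_metrics(y, p))
    if (!is.nan(rp$f1)) {
      expect_equal(rp$f1, f1_from_pr(rp$precision, rp$recall), tolerance = 1e-9)
      expect_equal(rp$f1, 100 * 2 * rp$tp / (2 * rp$tp + rp$fp + rp$fn),
                   tolerance = 1e-9)
    }
  }
})

test_that("McNemar statistic and symmetry", {
  r <- mcnemar(15, 5)
  expect_equal(r$chi2, 4.05, tolerance = 1e-9)
  expect_equal(r$p, pchisq(4.05, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(mcnemar(10, 10)$chi2, 0.05, tolerance = 1e-9)
  expect_equal(mcnemar(7, 19)$chi2, mcnemar(19, 7)$chi2)
  expect_error(mcnemar(0, 0), "discordant")
})

test_that("Friedman test matches closed form and the stats oracle", {
  m <- matrix(rep(c(1, 2, 3), each = 10), 10, 3)  # identical ordering
  expect_equal(friedman(m)$chi2, 20, tolerance = 1e-12)
  expect_equal(friedman(matrix(5, 6, 3))$chi2, 0)
  expect_equal(friedman(matrix(5, 6, 3))$p, 1)

  set.seed(31)
  for (i in 1:5) {
    mm <- matrix(sample(1:4, 8 * 4, replace = TRUE), 8, 4)  # with ties
    ours <- friedman(mm)
    ref <- stats::friedman.test(mm)
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-9)
  }

  # invariant to monotone per-block transformations
  set.seed(32)
  mm <- matrix(rnorm(30), 10, 3)
  expect_equal(friedman(mm)$chi2, friedman(exp(mm))$chi2, tolerance = 1e-12)
})

test_that("Wilcoxon signed-rank: exact enumeration, approximation, BH", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), "greater")$p, 0.125)
  expect_equal(wilcoxon_signed_rank(c(-1, 1, -2, 2))$p, 1.0)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")

  set.seed(33)
  for (i in 1:5) {
    d <- round(rnorm(8), 2)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next  # oracle requires no ties
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
  # normal approximation with continuity correction above the exact cutoff
  set.seed(34)
  d <- rnorm(25, 0.3)
  ours <- wilcoxon_signed_rank(d)
  ref <- stats::wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_false(ours$exact)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)

  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03),
               tolerance = 1e-12)
  set.seed(35)
  p <- runif(12)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
  tab <- wilcoxon_bh(list(a = c(1, 2, 3, -1), b = c(2, 3, 4, 5)))
  expect_true(all(tab$p_adj >= tab$p))
})

test_that("Cliff's delta matches brute force", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(0, 0, 0)), 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cliffs_delta(c(1, 2), c(1, 3)), -0.25)
  set.seed(36)
  x <- rnorm(7); y <- rnorm(9)
  brute <- 0
  for (xi in x) for (yj in y) brute <- brute + sign(xi - yj)
  expect_equal(cliffs_delta(x, y), brute / 63, tolerance = 1e-12)
  expect_lte(abs(cliffs_delta(x, y)), 1)
})

test_that("index baselines classify synthetic segments as designed", {
  sim <- tiny_sim(n_channels = 2, duration_s = 100, fs = 8, low_fraction = 0,
                  minor_motion_rate = 0, seed = 40)
  rec <- sim$recording
  # build one coupling-loss channel: uncorrelated noise, one saturated channel
  set.seed(41)
  n <- nrow(rec$intensity)
  rec$intensity[, 2, ] <- exp(-matrix(rnorm(2 * n, 0, 0.05), ncol = 2))
  segs <- segment_channels(rec, 2)
  truth <- ifelse(segs$channel_index == 0, "high", "low")
  bl <- suppressWarnings(run_baselines(rec, segs, truth))
  # clean stable intensity -> CV says high; uncorrelated noise -> SCI says low
  expect_true(all(bl$pred_cv[segs$channel_index == 0] == "high"))
  expect_true(all(bl$pred_sci[segs$channel_index == 1] == "low"))

  # saturated channel: CV ~ 0 (misses it) but SCI = 0 (flags it)
  rec$intensity[, 2, ] <- 1
  bl2 <- suppressWarnings(run_baselines(rec, segs, truth))
  expect_true(all(bl2$pred_cv[segs$channel_index == 1] == "high"))
  expect_true(all(bl2$pred_sci[segs$channel_index == 1] == "low"))

  # one-class truth surfaces undefined ratios
  w2 <- capture_warnings(confusion_metrics(rep("high", 4), bl2$pred_cv[1:4]))
  expect_match(w2, "undefined", all = FALSE)
})

test_that("class-share arithmetic is exact before rounding", {
  s <- summarize_label_counts(list(a = c(low = 3, high = 2),
                                   b = c(low = 1, high = 4)))
  expect_equal(s$low_pct[s$dataset == "a"], 60)
  expect_equal(s$n[s$dataset == "combined"], 10)
  expect_equal(s$high_pct[s$dataset == "combined"], 60)
})
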