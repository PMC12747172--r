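test_that("class weights follow the inverse-frequency formula", {
  expect_equal(unname(class_weights(rep(c("high", "low"), 10))), c(1, 1))
  w <- class_weights(c(rep("high", 75), rep("low", 25)))
  expect_equal(unname(w), c(100 / 150, 100 / 50), tolerance = 1e-9)
  expect_error(class_weights(rep("high", 5)), "both classes")
})

test_that("make_split partitions subjects without leakage", {
  set.seed(20)
  meta <- data.frame(subject_id = rep(sprintf("P%02d", 1:20), each = 10),
                     label = sample(c("high", "low"), 200, replace = TRUE))
  # no holdout: 20 development subjects over 10 folds -> 2 per fold
  plan0 <- make_split(meta, k = 10, holdout_frac = 0, seed = 3)
  expect_true(all(lengths(plan0$folds) == 2))
  expect_setequal(unlist(plan0$folds), plan0$development_subjects)
  expect_equal(anyDuplicated(unlist(plan0$folds)), 0)

  plan <- make_split(meta, k = 10, holdout_frac = 0.1, seed = 3)
  expect_no_subject_overlap(plan$holdout_subjects, plan$development_subjects)
  for (f in plan$folds) {
    expect_no_subject_overlap(f, plan$holdout_subjects)
    expect_no_subject_overlap(f, setdiff(plan$development_subjects, f))
  }
  # determinism
  expect_identical(plan, make_split(meta, k = 10, holdout_frac = 0.1, seed = 3))
  expect_error(make_split(meta[1:50, ], k = 10), "folds")
})

test_that("split_80_10_10 is subject-disjoint, stratified and deterministic", {
  set.seed(21)
  meta <- data.frame(subject_id = rep(sprintf("P%02d", 1:10), each = 8),
                     label = sample(c("high", "low"), 80, replace = TRUE))
  sp <- split_80_10_10(meta, seed = 5)
  expect_length(sp$train_subjects, 8)
  expect_length(sp$val_subjects, 1)
  expect_length(sp$test_subjects, 1)
  expect_no_subject_overlap(sp$train_subjects, sp$val_subjects)
  expect_no_subject_overlap(sp$train_subjects, sp$test_subjects)
  expect_no_subject_overlap(sp$val_subjects, sp$test_subjects)
  expect_identical(sp, split_80_10_10(meta, seed = 5))
  expect_error(split_80_10_10(meta[1:16, ], seed = 5), "10 subjects")
})

test_that("training learns separable toy images, reproducibly", {
  toy <- toy_image_set(n_subjects = 8, per_subject = 6, size = 16, seed = 2)
  cfg <- train_config(input_size = 16, filters = c(4, 8, 8), max_epochs = 25,
                      patience = 20, translate_px = c(2, 1), seed = 9,
                      crop_top_rows = NULL)
  tr_s <- sprintf("T%02d", 1:6)
  va_s <- sprintf("T%02d", 7:8)
  m1 <- train_classifier(toy$images, toy$meta, tr_s, va_s, cfg)
  expect_gte(m1$val_accuracy, 0.9)
  # identical seed -> identical training curves
  m2 <- train_classifier(toy$images, toy$meta, tr_s, va_s, cfg)
  expect_identical(m1$log, m2$log)
  expect_error(train_classifier(toy$images, toy$meta, tr_s, c("T01", "T07"), cfg),
               "leakage")
})

test_that("shuffled labels train to chance-level validation accuracy", {
  toy <- toy_image_set(n_subjects = 8, per_subject = 6, size = 16, seed = 3)
  set.seed(33)
  toy$meta$label <- sample(toy$meta$label)
  cfg <- train_config(input_size = 16, filters = c(4, 8, 8), max_epochs = 6,
                      patience = 5, seed = 10, crop_top_rows = NULL)
  m <- train_classifier(toy$images, toy$meta, sprintf("T%02d", 1:6),
                        sprintf("T%02d", 7:8), cfg)
  expect_gte(m$val_accuracy, 0.3)
  expect_lte(m$val_accuracy, 0.8)
})

test_that("early stopping halts before max_epochs on a flat monitor", {
  toy <- toy_image_set(n_subjects = 4, per_subject = 4, size = 16, seed = 4)
  # constant validation images -> accuracy can never improve after epoch 1
  idx_va <- which(toy$meta$subject_id == "T04")
  for (i in idx_va) toy$images[[i]] <- toy$images[[idx_va[1]]]
  toy$meta$label[idx_va] <- "high"
  cfg <- train_config(input_size = 16, filters = c(2, 2, 2), max_epochs = 30,
                      patience = 2, seed = 11, crop_top_rows = NULL)
  m <- train_classifier(toy$images, toy$meta, sprintf("T%02d", 1:3), "T04", cfg)
  expect_lt(nrow(m$log), 30)
})

test_that("prediction is batch-invariant, normalized and shape-checked", {
  toy <- toy_image_set(n_subjects = 6, per_subject = 4, size = 16, seed = 5)
  cfg <- train_config(input_size = 16, filters = c(2, 4, 4), max_epochs = 3,
                      patience = 2, seed = 12, crop_top_rows = NULL)
  m <- train_classifier(toy$images, toy$meta, sprintf("T%02d", 1:5), "T06", cfg)
  p_all <- predict_quality(m, toy$images, batch = 7)
  p_one <- predict_quality(m, toy$images[[5]])
  expect_equal(p_all$p_low[5], p_one$p_low, tolerance = 1e-12)
  expect_true(all(p_all$p_low >= 0 & p_all$p_low <= 1))
  expect_error(predict_quality(m, list(matrix(0, 4, 4))), "images")

  # checkpoint round trip preserves predictions exactly
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  p2 <- predict_quality(m2, toy$images[1:4])
  expect_equal(p2$p_low, p_all$p_low[1:4], tolerance = 1e-9)
})

test_that("channel quality percentages quantize correctly", {
  pred <- data.frame(subject_id = "S01",
                     channel_index = rep(0:1, each = 5),
                     label = c("high", "high", "high", "low", "low",
                               rep("low", 5)))
  pct <- channel_quality_percentage(pred)
  expect_equal(pct$quality_pct, c(60, 0))
  pred$label <- "high"
  expect_equal(channel_quality_percentage(pred)$quality_pct, c(100, 100))
})

test_that("CNN gradients match finite differences", {
  w <- fnirsqc:::cnn_init(16, filters = c(2, 3, 4), seed = 5)
  idx <- lapply(1:3, function(l) fnirsqc:::conv_idx(c(16, 8, 4)[l], c(16, 8, 4)[l],
                                                    c(3, 2, 3)[l]))
  set.seed(6)
  X <- array(runif(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  y <- c(1, 2, 1, 2); cw <- c(high = 1.2, low = 0.8)
  lg <- fnirsqc:::cnn_loss_grad(w, X, y, cw, 1e-4, idx)
  for (nm in c("W1", "b1", "g1", "be2", "W3", "Wd", "bd")) {
    g <- lg$grads[[nm]]
    i <- which.max(abs(g))
    eps <- 1e-6
    wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
    wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
    num <- (fnirsqc:::cnn_loss_grad(wp, X, y, cw, 1e-4, idx)$loss -
              fnirsqc:::cnn_loss_grad(wm, X, y, cw, 1e-4, idx)$loss) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})
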