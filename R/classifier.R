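# Training protocol: subject-wise stratified splits, class-weighted training
# of the compact CNN, prediction and channel-level aggregation.

#' Training configuration
#'
#' Defaults follow the training protocol used for scalogram quality
#' classification: Adam with initial learning rate 1e-4 and a tenfold
#' learning-rate multiplier for newly initialised layers (all layers, in a
#' from-scratch model), batch 32, at most 50 epochs, L2 weight decay 1e-4,
#' early stopping after 15 epochs without validation-accuracy improvement,
#' on-the-fly augmentation (random translation, scaling, cropping) and
#' inverse-frequency class weights.
#'
#' @param lr initial learning rate.
#' @param fresh_layer_lr_factor learning-rate multiplier applied to newly
#'   initialised layers; every layer of the from-scratch model is new, so the
#'   effective rate is `lr * fresh_layer_lr_factor`.
#' @param batch batch size.
#' @param max_epochs maximum epochs.
#' @param l2 L2 weight decay.
#' @param patience early-stopping patience (epochs, `< max_epochs`).
#' @param input_size CNN input side in px; standardized 224 px images are
#'   bilinearly downsampled to this size (64 by default to fit CPU budgets).
#' @param filters channels of the three conv blocks.
#' @param translate_px augmentation translation extents (horizontal,
#'   vertical) in 224-px units; vertical kept small so the cardiac anchor row
#'   is not destroyed.
#' @param scale_range augmentation scale range.
#' @param class_weighting logical, use inverse-frequency class weights.
#' @param crop_top_rows keep only the top rows of the standardized image
#'   before downsampling (default 64): the cardiac anchor row sits near the
#'   top and rows below the CWT grid are structural zero padding, so cropping
#'   preserves full frequency resolution at a fraction of the compute.
#' @param input_norm input normalization: `"image_z"` (per-image
#'   z-scoring, the default; channel-pooled scalogram normalization leaves
#'   large brightness differences between images that carry no quality
#'   information) or `"none"`.
#' @param seed training seed.
#' @return list of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, fresh_layer_lr_factor = 10, batch = 32,
                         max_epochs = 50, l2 = 1e-4, patience = 15,
                         input_size = 64, filters = c(8, 16, 32),
                         translate_px = c(8, 2), scale_range = c(0.9, 1.1),
                         class_weighting = TRUE, input_norm = "image_z",
                         crop_top_rows = 64, seed = 1) {
  stopifnot(lr > 0, batch > 0, max_epochs > 0, l2 >= 0, patience >= 1,
            patience < max_epochs)
  structure(as.list(environment()), class = "train_config")
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (2 N_c)`; mean 1 for balanced labels. Errors when a class is
#' absent.
#'
#' @param labels character vector of "high"/"low".
#' @return named numeric vector `c(high = ..., low = ...)`.
#' @export
class_weights <- function(labels) {
  n_high <- sum(labels == "high"); n_low <- sum(labels == "low")
  if (n_high == 0 || n_low == 0) stopf("both classes must be present")
  n <- n_high + n_low
  c(high = n / (2 * n_high), low = n / (2 * n_low))
}

subject_low_fraction <- function(meta) {
  subj <- unique(meta$subject_id)
  frac <- vapply(subj, function(s) mean(meta$label[meta$subject_id == s] == "low"),
                 numeric(1))
  data.frame(subject_id = subj, low_frac = frac)
}

stratified_order <- function(sl, seed) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  jit <- stats::runif(nrow(sl), 0, 1e-6)
  sl$subject_id[order(sl$low_frac + jit, sl$subject_id)]
}

#' Subject-wise stratified split plan (holdout + k folds)
#'
#' Splits subjects into an independent holdout set and a development set, and
#' partitions the development subjects into `k` cross-validation folds by
#' greedy snake assignment over subjects ordered by their low-quality
#' fraction, so fold class balance is approximately stratified. A subject's
#' samples never span train and validation. Deterministic given `seed`.
#'
#' @param meta data frame with one row per sample: `subject_id`, `label`.
#' @param k number of folds.
#' @param holdout_frac fraction of subjects held out (default 0.1).
#' @param seed RNG seed.
#' @return list with `holdout_subjects`, `development_subjects`, `folds`
#'   (list of validation-subject vectors).
#' @export
make_split <- function(meta, k = 10, holdout_frac = 0.1, seed = 1) {
  sl <- subject_low_fraction(meta)
  n <- nrow(sl)
  ord <- stratified_order(sl, derive_seed(seed, 101))
  n_hold <- if (holdout_frac <= 0) 0L else max(1, round(holdout_frac * n))
  holdout <- if (n_hold > 0) {
    ord[unique(round(seq(1, n, length.out = n_hold + 2))[2:(n_hold + 1)])]
  } else character()
  dev <- setdiff(ord, holdout)
  if (length(dev) < k) stopf("fewer development subjects (%d) than folds (%d)",
                             length(dev), k)
  fold_of <- rep(c(seq_len(k), rev(seq_len(k))), length.out = length(dev))
  folds <- lapply(seq_len(k), function(f) dev[fold_of == f])
  list(holdout_subjects = holdout, development_subjects = dev, folds = folds)
}

#' Subject-wise stratified 80:10:10 partition
#'
#' @param meta data frame with `subject_id`, `label` per sample.
#' @param seed RNG seed.
#' @return list with `train_subjects`, `val_subjects`, `test_subjects`.
#' @export
split_80_10_10 <- function(meta, seed = 1) {
  sl <- subject_low_fraction(meta)
  n <- nrow(sl)
  if (n < 10) stopf("need at least 10 subjects for an 80:10:10 subject split")
  ord <- stratified_order(sl, derive_seed(seed, 202))
  n_test <- max(1, round(0.1 * n))
  n_val <- max(1, round(0.1 * n))
  test_pos <- unique(round(seq(1, n, length.out = n_test + 2))[2:(n_test + 1)])
  test <- ord[test_pos]
  rest <- setdiff(ord, test)
  val_pos <- unique(round(seq(1, length(rest), length.out = n_val + 2))[2:(n_val + 1)])
  val <- rest[val_pos]
  train <- setdiff(rest, val)
  list(train_subjects = train, val_subjects = val, test_subjects = test)
}

assemble_batch <- function(images, idxs, size, augment_cfg = NULL,
                           full_size = 224, input_norm = "image_z",
                           crop_top_rows = NULL) {
  if (!(is.numeric(crop_top_rows) && length(crop_top_rows) == 1 &&
          is.finite(crop_top_rows))) {
    crop_top_rows <- NULL
  }
  X <- array(0, c(size, size, 3, length(idxs)))
  for (j in seq_along(idxs)) {
    img <- images[[idxs[j]]]
    if (!is.null(crop_top_rows) && crop_top_rows < dim(img)[1]) {
      img <- img[seq_len(crop_top_rows), , , drop = FALSE]
    }
    img <- resize_image(img, size)
    if (!is.null(augment_cfg)) {
      img <- augment_image(img, augment_cfg$translate_px, augment_cfg$scale_range,
                           full_size = full_size)
    }
    if (identical(input_norm, "image_z")) {
      img <- (img - mean(img)) / max(stats::sd(img), 1e-6)
    }
    X[, , , j] <- img
  }
  X
}

#' Train the compact CNN quality classifier
#'
#' Trains on the samples of `train_subjects`, monitors accuracy on
#' `val_subjects` (subject-disjoint by construction; asserted), and early-stops
#' when validation accuracy has not improved for `config$patience` epochs
#' (ties broken by lower validation loss). The best-epoch weights are
#' returned. Fully seeded: identical seeds give identical training curves.
#'
#' @param images list of image arrays (`[H, W, 3]`, values in `[0, 1]`).
#' @param meta data frame aligned with `images`: `subject_id`, `label`
#'   (and optionally channel/segment indices).
#' @param train_subjects,val_subjects subject id vectors.
#' @param config a [train_config()].
#' @return list of class `fnirsqc_model`: `weights`, `config`, `classes`,
#'   `log` (per-epoch data frame), `best_epoch`.
#' @export
train_classifier <- function(images, meta, train_subjects, val_subjects,
                             config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  if (length(intersect(train_subjects, val_subjects))) {
    stopf("subject leakage: train and validation subject sets intersect")
  }
  tr <- which(meta$subject_id %in% train_subjects)
  va <- which(meta$subject_id %in% val_subjects)
  if (!length(tr)) stopf("empty training fold")
  if (!length(va)) stopf("empty validation fold")
  full_size <- dim(images[[1]])[1]
  # crop + downsample once; augmentation operates at input scale
  images <- lapply(images, function(img) {
    ct <- config$crop_top_rows
    if (is.numeric(ct) && length(ct) == 1 && is.finite(ct) &&
          ct < dim(img)[1]) {
      img <- img[seq_len(ct), , , drop = FALSE]
    }
    resize_image(img, config$input_size)
  })
  classes <- c("high", "low")
  y_tr <- match(meta$label[tr], classes)
  y_va <- match(meta$label[va], classes)
  cw <- if (config$class_weighting) class_weights(meta$label[tr]) else c(high = 1, low = 1)

  size <- config$input_size
  sizes <- c(size, size / 2, size / 4)
  cins <- c(3, config$filters[1], config$filters[2])
  idx_list <- lapply(1:3, function(l) conv_idx(sizes[l], sizes[l], cins[l]))

  w <- cnn_init(size, config$filters, seed = derive_seed(config$seed, 1))
  st <- adam_init(w)
  bn <- bn_init(config$filters)
  lr_eff <- config$lr * config$fresh_layer_lr_factor
  aug <- list(translate_px = config$translate_px, scale_range = config$scale_range)

  Xva <- assemble_batch(images, va, size, input_norm = config$input_norm,
                        crop_top_rows = config$crop_top_rows)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), val_acc = numeric())
  best <- list(acc = -Inf, loss = Inf, w = w, bn = bn, epoch = 0)
  wait <- 0
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  for (epoch in seq_len(config$max_epochs)) {
    set.seed(derive_seed(config$seed, 1000 + epoch))
    perm <- sample(seq_along(tr))
    tl <- 0; nb <- 0
    for (b0 in seq(1, length(perm), by = config$batch)) {
      bi <- perm[b0:min(b0 + config$batch - 1, length(perm))]
      X <- assemble_batch(images, tr[bi], size, aug, full_size = full_size,
                          input_norm = config$input_norm,
                          crop_top_rows = config$crop_top_rows)
      lg <- cnn_loss_grad(w, X, y_tr[bi], cw, config$l2, idx_list, bn = bn)
      bn <- lg$bn
      stp <- adam_step(w, lg$grads, st, lr_eff)
      w <- stp$w; st <- stp$st
      tl <- tl + lg$loss; nb <- nb + 1
    }
    fv <- cnn_forward(w, Xva, idx_list, bn = bn, train = FALSE)
    pred <- max.col(t(fv$probs))
    acc <- mean(pred == y_va)
    vloss <- mean(-log(pmax(fv$probs[cbind(y_va, seq_along(y_va))], 1e-12)))
    log <- rbind(log, data.frame(epoch = epoch, train_loss = tl / nb,
                                 val_loss = vloss, val_acc = acc))
    # the patience counter follows validation accuracy alone; accuracy ties
    # with lower loss update the retained best model but do not reset it
    if (acc > best$acc) {
      best <- list(acc = acc, loss = vloss, w = w, bn = bn, epoch = epoch)
      wait <- 0
    } else {
      if (acc == best$acc && vloss < best$loss) {
        best <- list(acc = acc, loss = vloss, w = w, bn = bn, epoch = epoch)
      }
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  structure(list(weights = best$w, bn = best$bn, config = config,
                 classes = classes, log = log, best_epoch = best$epoch,
                 val_accuracy = best$acc),
            class = "fnirsqc_model")
}

#' @export
print.fnirsqc_model <- function(x, ...) {
  cat(sprintf("<fnirsqc_model: %d-px input, best epoch %d, val accuracy %.3f>\n",
              x$config$input_size, x$best_epoch, x$val_accuracy))
  invisible(x)
}

#' Predict segment quality with a trained model
#'
#' Deterministic given the model; images are downsampled to the model's input
#' size. The label is the argmax class and `p_low` the softmax probability of
#' the low-quality class. Batching does not change results.
#'
#' @param model an `fnirsqc_model`.
#' @param images list of image arrays `[H, W, 3]` (or a single array).
#' @param batch batch size for the forward passes.
#' @return data frame with `label` and `p_low`.
#' @export
predict_quality <- function(model, images, batch = 64) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  bad <- vapply(images, function(im) length(dim(im)) != 3 || dim(im)[3] != 3,
                logical(1))
  if (any(bad)) stopf("images must be [H x W x 3] arrays")
  size <- model$config$input_size
  sizes <- c(size, size / 2, size / 4)
  cins <- c(3, model$config$filters[1], model$config$filters[2])
  idx_list <- lapply(1:3, function(l) conv_idx(sizes[l], sizes[l], cins[l]))
  out <- vector("list", length(images))
  for (b0 in seq(1, length(images), by = batch)) {
    bi <- b0:min(b0 + batch - 1, length(images))
    X <- assemble_batch(images, bi, size,
                        input_norm = model$config$input_norm %||% "image_z",
                        crop_top_rows = model$config$crop_top_rows)
    fv <- cnn_forward(model$weights, X, idx_list, bn = model$bn, train = FALSE)
    out[bi] <- lapply(seq_along(bi), function(j) fv$probs[, j])
  }
  p <- do.call(rbind, out)
  data.frame(label = model$classes[max.col(p)], p_low = p[, 2])
}

#' Channel quality percentage from segment predictions
#'
#' `100 * #high / #segments` per channel.
#'
#' @param pred data frame with `subject_id`, `channel_index`, `label`.
#' @return data frame with `subject_id`, `channel_index`, `quality_pct`.
#' @export
channel_quality_percentage <- function(pred) {
  key <- interaction(pred$subject_id, pred$channel_index, drop = TRUE)
  first <- !duplicated(key)
  pct <- tapply(pred$label == "high", key, mean) * 100
  data.frame(subject_id = pred$subject_id[first],
             channel_index = pred$channel_index[first],
             quality_pct = as.numeric(pct[as.character(key[first])]))
}

#' Save / load a model checkpoint as JSON (text-only, seed and config embedded)
#' @param model an `fnirsqc_model`.
#' @param path checkpoint path (`.json`).
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config), classes = model$classes,
              best_epoch = model$best_epoch, val_accuracy = model$val_accuracy,
              log = model$log,
              bn = list(mean = model$bn$mean, var = model$bn$var,
                        seen = isTRUE(model$bn$seen)),
              weights = lapply(model$weights, function(w) {
                if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
                else list(dim = length(w), data = as.numeric(w))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2]) else as.numeric(w$data)
  })
  cfg <- obj$config
  cfg$filters <- as.numeric(cfg$filters)
  cfg$translate_px <- as.numeric(cfg$translate_px)
  cfg$scale_range <- as.numeric(cfg$scale_range)
  class(cfg) <- "train_config"
  bn <- list(mean = lapply(obj$bn$mean, as.numeric),
             var = lapply(obj$bn$var, as.numeric),
             seen = isTRUE(obj$bn$seen))
  structure(list(weights = weights, bn = bn, config = cfg, classes = obj$classes,
                 log = as.data.frame(obj$log), best_epoch = obj$best_epoch,
                 val_accuracy = obj$val_accuracy),
            class = "fnirsqc_model")
}
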