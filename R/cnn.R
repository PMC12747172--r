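# Compact convolutional network in vectorised base R. Three conv-ReLU-pool
# blocks, global average pooling and a 2-way softmax head; im2col + matrix
# multiplication for the convolutions, Adam optimiser, weighted cross-entropy,
# L2 decay, on-the-fly augmentation and early stopping. Deliberately small:
# the classification problem operates on standardized scalograms whose
# discriminative structure is coarse, and training must fit a single CPU.

conv_idx <- function(H, W, C) {
  # im2col gather indices into the zero-padded [H+2, W+2, C] array, 3x3 kernel,
  # stride 1. Rows: output pixel (h fastest); cols: (ki, kj, ci) with ki fastest.
  Hp <- H + 2; Wp <- W + 2
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9 * C)
  col <- 1
  for (ci in seq_len(C)) {
    for (kj in 1:3) {
      for (ki in 1:3) {
        idx[, col] <- (h + ki - 1) + (w + kj - 2) * Hp + (ci - 1) * Hp * Wp
        col <- col + 1
      }
    }
  }
  idx
}

conv_forward <- function(X, W, b, idx) {
  d <- dim(X); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Hp <- H + 2; Wp <- Wd + 2
  Xp <- array(0, c(Hp, Wp, C, N))
  Xp[2:(H + 1), 2:(Wd + 1), , ] <- X
  HW <- H * Wd
  cols <- matrix(0, HW * N, ncol(idx))
  stride <- Hp * Wp * C
  for (n in seq_len(N)) {
    xn <- Xp[, , , n]
    cols[(n - 1) * HW + seq_len(HW), ] <- xn[idx]
  }
  Y <- cols %*% W
  Y <- Y + rep(b, each = nrow(Y))
  Cout <- length(b)
  out <- array(0, c(H, Wd, Cout, N))
  for (n in seq_len(N)) {
    out[, , , n] <- array(Y[(n - 1) * HW + seq_len(HW), ], c(H, Wd, Cout))
  }
  list(out = out, cols = cols, dims = d)
}

conv_backward <- function(dOut, cache, W) {
  d <- cache$dims; H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * Wd
  Cout <- dim(dOut)[3]
  dYm <- matrix(0, HW * N, Cout)
  for (n in seq_len(N)) {
    dYm[(n - 1) * HW + seq_len(HW), ] <- matrix(dOut[, , , n], HW, Cout)
  }
  dW <- crossprod(cache$cols, dYm)
  db <- colSums(dYm)
  dcols <- dYm %*% t(W)
  dXp <- array(0, c(H + 2, Wd + 2, C, N))
  col <- 1
  for (ci in seq_len(C)) {
    for (kj in 1:3) {
      for (ki in 1:3) {
        patch <- array(dcols[, col], c(H, Wd, N))
        rows <- ki:(ki + H - 1); cls <- kj:(kj + Wd - 1)
        dXp[rows, cls, ci, ] <- dXp[rows, cls, ci, ] + patch
        col <- col + 1
      }
    }
  }
  list(dX = dXp[2:(H + 1), 2:(Wd + 1), , , drop = FALSE], dW = dW, db = db)
}

# 2x2 max pooling; gradient routed to the first maximal corner
pool_forward <- function(X, keep_masks = FALSE) {
  d <- dim(X)
  ho <- seq(1, d[1], 2); he <- ho + 1
  wo <- seq(1, d[2], 2); we <- wo + 1
  s <- list(X[ho, wo, , , drop = FALSE], X[he, wo, , , drop = FALSE],
            X[ho, we, , , drop = FALSE], X[he, we, , , drop = FALSE])
  out <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  if (!keep_masks) return(list(out = out))
  taken <- array(FALSE, dim(out))
  masks <- vector("list", 4)
  for (k in 1:4) {
    m <- (s[[k]] == out) & !taken
    masks[[k]] <- m
    taken <- taken | m
  }
  list(out = out, masks = masks)
}

pool_backward <- function(dY, in_dim, masks) {
  dX <- array(0, in_dim)
  ho <- seq(1, in_dim[1], 2); he <- ho + 1
  wo <- seq(1, in_dim[2], 2); we <- wo + 1
  dX[ho, wo, , ] <- dY * masks[[1]]
  dX[he, wo, , ] <- dY * masks[[2]]
  dX[ho, we, , ] <- dY * masks[[3]]
  dX[he, we, , ] <- dY * masks[[4]]
  dX
}

#' Initialise a compact CNN
#'
#' He-initialised weights for three 3x3 conv blocks (`filters` channels),
#' time-axis (column) average pooling that preserves the frequency axis --
#' the cardiac band is anchored to a fixed image row, so row position is the
#' signal -- and a dense softmax head.
#'
#' @param input_size square input side (divisible by 8).
#' @param filters channel counts of the three blocks.
#' @param n_classes output classes (2).
#' @param in_channels input channels (3 for RGB).
#' @param seed RNG seed.
#' @return list of weight tensors.
#' @keywords internal
cnn_init <- function(input_size, filters = c(8, 16, 32), n_classes = 2,
                     in_channels = 3, seed = 1) {
  if (input_size %% 8 != 0) stopf("input_size must be divisible by 8")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cin <- c(in_channels, filters[1], filters[2])
  w <- list()
  for (l in 1:3) {
    fan_in <- 9 * cin[l]
    w[[paste0("W", l)]] <- matrix(stats::rnorm(fan_in * filters[l], 0,
                                               sqrt(2 / fan_in)),
                                  fan_in, filters[l])
    w[[paste0("b", l)]] <- numeric(filters[l])
    w[[paste0("g", l)]] <- rep(1, filters[l])   # batch-norm gain
    w[[paste0("be", l)]] <- numeric(filters[l]) # batch-norm shift
  }
  n_feat <- 2 * (input_size / 8) * filters[3]
  w$Wd <- matrix(stats::rnorm(n_feat * n_classes, 0, sqrt(2 / n_feat)),
                 n_feat, n_classes)
  w$bd <- numeric(n_classes)
  w
}

# per-channel moments over (H, W, N) of an [H, W, C, N] array
chan_moments <- function(x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
  mu <- colMeans(m)
  va <- colMeans(m^2) - mu^2
  list(mu = mu, va = va)
}

chan_sweep <- function(x, v, op = `*`) {
  # broadcast a per-channel vector over dim 3 of [H, W, C, N]
  d <- dim(x)
  op(x, aperm(array(rep(v, each = d[1] * d[2]), c(d[1], d[2], d[3], d[4])),
              c(1, 2, 3, 4)))
}

bn_init <- function(filters) {
  list(mean = lapply(filters, function(f) numeric(f)),
       var = lapply(filters, function(f) rep(1, f)),
       seen = FALSE)
}

cnn_forward <- function(w, X, idx_list, bn = NULL, train = FALSE,
                        keep_cache = FALSE, bn_momentum = 0.9) {
  caches <- list()
  eps <- 1e-5
  a <- X
  for (l in 1:3) {
    cv <- conv_forward(a, w[[paste0("W", l)]], w[[paste0("b", l)]], idx_list[[l]])
    r <- cv$out
    # batch normalisation per output channel
    if (train || is.null(bn) || !isTRUE(bn$seen)) {
      mo <- chan_moments(r)
      if (train && !is.null(bn)) {
        if (!isTRUE(bn$seen)) {
          bn$mean[[l]] <- mo$mu; bn$var[[l]] <- mo$va
        } else {
          bn$mean[[l]] <- bn_momentum * bn$mean[[l]] + (1 - bn_momentum) * mo$mu
          bn$var[[l]] <- bn_momentum * bn$var[[l]] + (1 - bn_momentum) * mo$va
        }
      }
    } else {
      mo <- list(mu = bn$mean[[l]], va = bn$var[[l]])
    }
    istd <- 1 / sqrt(mo$va + eps)
    xhat <- chan_sweep(chan_sweep(r, mo$mu, `-`), istd)
    rb <- chan_sweep(xhat, w[[paste0("g", l)]])
    rb <- chan_sweep(rb, w[[paste0("be", l)]], `+`)
    mask <- rb > 0
    rb[!mask] <- 0
    p <- pool_forward(rb, keep_masks = keep_cache)
    if (keep_cache) {
      caches[[l]] <- list(conv = cv, mask = mask, relu_dim = dim(rb),
                          xhat = xhat, istd = istd, pool_masks = p$masks)
    }
    a <- p$out
  }
  if (train && !is.null(bn) && !isTRUE(bn$seen)) bn$seen <- TRUE
  d <- dim(a)
  # pool over time (columns) only, keeping the anchored frequency axis; both
  # first and second moments, so the head can read temporal intermittency
  # (a band-passed noise burst and a stable cardiac ridge share the mean but
  # not the variance along time)
  ap <- aperm(a, c(2, 1, 3, 4))
  hf <- d[1] * d[3]
  m1 <- matrix(colMeans(matrix(ap, d[2], hf * d[4])), hf, d[4])
  m2 <- matrix(colMeans(matrix(ap^2, d[2], hf * d[4])), hf, d[4])
  feat <- rbind(m1, m2)
  logits <- crossprod(w$Wd, feat) + w$bd
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), `/`)
  list(probs = probs, feat = feat, gap_in = a, gap_dim = d, caches = caches,
       bn = bn)
}

cnn_loss_grad <- function(w, X, y, cw, l2, idx_list, bn = NULL) {
  # y: integer class in 1..2; cw: per-class weights
  fw <- cnn_forward(w, X, idx_list, bn = bn, train = TRUE, keep_cache = TRUE)
  N <- ncol(fw$probs)
  wi <- cw[y]
  sw <- sum(wi)
  py <- fw$probs[cbind(y, seq_len(N))]
  loss <- sum(wi * -log(pmax(py, 1e-12))) / sw
  l2pen <- 0
  for (nm in c("W1", "W2", "W3", "Wd")) l2pen <- l2pen + sum(w[[nm]]^2)
  loss <- loss + l2 / 2 * l2pen
  dlogits <- fw$probs
  dlogits[cbind(y, seq_len(N))] <- dlogits[cbind(y, seq_len(N))] - 1
  dlogits <- sweep(dlogits, 2, wi, `*`) / sw
  g <- list()
  g$Wd <- fw$feat %*% t(dlogits) + l2 * w$Wd
  g$bd <- rowSums(dlogits)
  dfeat <- w$Wd %*% dlogits
  d <- fw$gap_dim
  hf <- d[1] * d[3]
  spread_t <- function(dm) {
    aperm(array(rep(as.numeric(dm) / d[2], each = d[2]),
                c(d[2], d[1], d[3], d[4])),
          c(2, 1, 3, 4))
  }
  da <- spread_t(dfeat[seq_len(hf), , drop = FALSE]) +
    2 * fw$gap_in * spread_t(dfeat[hf + seq_len(hf), , drop = FALSE])
  chan_sum <- function(x) {
    dd <- dim(x)
    colSums(matrix(aperm(x, c(1, 2, 4, 3)), dd[1] * dd[2] * dd[4], dd[3]))
  }
  for (l in 3:1) {
    ca <- fw$caches[[l]]
    dy <- pool_backward(da, ca$relu_dim, ca$pool_masks)
    dy[!ca$mask] <- 0
    # batch-norm backward (batch statistics)
    g[[paste0("g", l)]] <- chan_sum(dy * ca$xhat)
    g[[paste0("be", l)]] <- chan_sum(dy)
    dxhat <- chan_sweep(dy, w[[paste0("g", l)]])
    m <- prod(dim(dy)[c(1, 2, 4)])
    centred <- chan_sweep(dxhat, chan_sum(dxhat) / m, `-`)
    dr <- chan_sweep(centred - chan_sweep(ca$xhat, chan_sum(dxhat * ca$xhat) / m),
                     ca$istd)
    bk <- conv_backward(dr, ca$conv, w[[paste0("W", l)]])
    g[[paste0("W", l)]] <- bk$dW + l2 * w[[paste0("W", l)]]
    g[[paste0("b", l)]] <- bk$db
    da <- bk$dX
  }
  list(loss = loss, grads = g, probs = fw$probs, bn = fw$bn)
}

adam_init <- function(w) {
  list(m = lapply(w, function(x) x * 0), v = lapply(w, function(x) x * 0), t = 0)
}

adam_step <- function(w, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(w)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(w = w, st = st)
}

warp_bilinear <- function(img, scale = 1, dx = 0, dy = 0) {
  # sample input at out/scale around the centre, shifted by (dx, dy) pixels;
  # zero outside the support
  d <- dim(img)
  H <- d[1]; W <- d[2]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r <- (seq_len(H) - cy) / scale + cy - dy
  c <- (seq_len(W) - cx) / scale + cx - dx
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  gather <- function(ri, ci) {
    ok_r <- ri >= 1 & ri <= H; ok_c <- ci >= 1 & ci <= W
    m <- array(0, d)
    if (any(ok_r) && any(ok_c)) {
      m[ok_r, ok_c, ] <- img[ri[ok_r], ci[ok_c], , drop = FALSE]
    }
    m
  }
  w00 <- outer(1 - fr, 1 - fc); w10 <- outer(fr, 1 - fc)
  w01 <- outer(1 - fr, fc); w11 <- outer(fr, fc)
  out <- gather(r0, c0) * as.numeric(w00) + gather(r0 + 1, c0) * as.numeric(w10) +
    gather(r0, c0 + 1) * as.numeric(w01) + gather(r0 + 1, c0 + 1) * as.numeric(w11)
  out
}

augment_image <- function(img, translate_px = c(8, 2), scale_range = c(0.9, 1.1),
                          full_size = 224) {
  d <- dim(img)
  f <- d[1] / full_size  # augmentation magnitudes specified at 224-px scale
  dx <- stats::runif(1, -translate_px[1], translate_px[1]) * f
  dy <- stats::runif(1, -translate_px[2], translate_px[2]) * f
  s <- stats::runif(1, scale_range[1], scale_range[2])
  warp_bilinear(img, s, dx, dy)
}

resize_image <- function(img, size) {
  d <- dim(img)
  if (d[1] == size && d[2] == size) return(img)
  out <- array(0, c(size, size, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- resize_bilinear(img[, , c], size, size)
  out
}
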