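#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a base seed
#'
#' All stochastic code in the package takes explicit seeds; nested components
#' (per subject, per channel, per epoch) derive their own stream from the base
#' seed with this helper so runs are reproducible and independent of call
#' order. Result is always in `[1, 2^31 - 2]`.
#'
#' @param seed integer base seed.
#' @param ... further integers identifying the sub-stream.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    h <- (h * 69069 + (as.numeric(p) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h %% 2147483646 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_format <- function(...) {
  stop(errorCondition(sprintf(...), class = c("fnirsqc_format_error", "error")))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

linear_resample_weights <- function(n_in, n_out, antialias = TRUE) {
  # triangle-kernel resampling weights with half-pixel centre alignment;
  # on shrink the kernel is widened by the scale factor (antialiasing, the
  # imresize convention), which degenerates to plain bilinear on upscale
  scale <- n_in / n_out
  s <- if (antialias && scale > 1) scale else 1
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * scale + 0.5  # source coordinate (1-based centres)
    j <- max(1, floor(x - s)):min(n_in, ceiling(x + s))
    w <- pmax(0, 1 - abs(j - x) / s)
    if (sum(w) == 0) { j <- clamp(round(x), 1, n_in); w <- 1 }
    W[i, j] <- w / sum(w)
  }
  W
}

#' Bilinear resampling of a matrix (antialiased on downscale)
#'
#' Resamples a numeric matrix to a new size with a triangle (linear) kernel
#' and half-pixel centre alignment. When shrinking, the kernel is widened by
#' the scale factor so thin structures (such as a one-ridge scalogram) are
#' averaged rather than aliased away -- the behaviour of standard image
#' resize routines. Used for the time-axis rescale of scalograms and for
#' downsampling classifier inputs.
#'
#' @param m numeric matrix.
#' @param out_rows,out_cols target dimensions.
#' @param antialias widen the kernel when shrinking (default TRUE).
#' @return numeric matrix of dimension `out_rows` x `out_cols`.
#' @export
resize_bilinear <- function(m, out_rows, out_cols, antialias = TRUE) {
  stopifnot(is.matrix(m), out_rows >= 1, out_cols >= 1)
  Wr <- linear_resample_weights(nrow(m), out_rows, antialias)
  Wc <- linear_resample_weights(ncol(m), out_cols, antialias)
  Wr %*% m %*% t(Wc)
}
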