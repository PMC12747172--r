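# Digital filtering primitives: Butterworth design, zero-phase filtering and
# Savitzky-Golay smoothing. No signal-processing package with these primitives
# is available in the dependency set, so they are implemented from the
# standard definitions (bilinear transform of the analog prototype; odd
# reflection padding and steady-state initial conditions for filtfilt).

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p) * rt
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Returns transfer-function coefficients of a Butterworth band-pass filter
#' designed by bilinear transform with frequency prewarping, following the
#' `butter(order, c(low, high))` convention (an order-`order` low-pass
#' prototype, hence `2 * order` poles).
#'
#' @param order prototype order (default 4).
#' @param low,high band edges in Hz, `0 < low < high < fs / 2`.
#' @param fs sampling rate in Hz.
#' @return list with numerator `b` and denominator `a`.
#' @export
butter_bandpass <- function(order = 4, low, high, fs) {
  stopifnot(order >= 1, fs > 0)
  if (!(low > 0 && high > low && high < fs / 2)) {
    stopf("band [%g, %g] Hz must lie strictly inside (0, %g) Hz", low, high, fs / 2)
  }
  n <- order
  # analog low-pass prototype (unit cutoff, all-pole)
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  gain <- 1
  # prewarped band edges
  w1 <- 2 * fs * tan(pi * low / fs)
  w2 <- 2 * fs * tan(pi * high / fs)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)
  # low-pass -> band-pass
  plp <- p * bw / 2
  pbp <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
  zbp <- rep(0 + 0i, n)
  gain <- gain * bw^n
  # bilinear transform
  fs2 <- 2 * fs
  pz <- (fs2 + pbp) / (fs2 - pbp)
  zz <- (fs2 + zbp) / (fs2 - zbp)
  gain <- gain * Re(prod(fs2 - zbp) / prod(fs2 - pbp))
  zz <- c(zz, rep(-1 + 0i, length(pz) - length(zz)))
  b <- Re(gain * poly_from_roots(zz))
  a <- Re(poly_from_roots(pz))
  list(b = b, a = a)
}

lfilter <- function(b, a, x, zi = NULL) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  z <- if (is.null(zi)) rep(0, nfilt - 1) else zi
  n <- length(x)
  y <- numeric(n)
  nz <- nfilt - 1
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1) {
      z[seq_len(nz - 1)] <- b[2:nz] * xi + z[2:nz] - a[2:nz] * yi
    }
    z[nz] <- b[nfilt] * xi - a[nfilt] * yi
    y[i] <- yi
  }
  y
}

lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  n <- nfilt - 1
  comp <- matrix(0, n, n)
  comp[1, ] <- -a[2:nfilt]
  if (n > 1) comp[cbind(2:n, 1:(n - 1))] <- 1
  solve(diag(n) - t(comp), b[2:nfilt] - a[2:nfilt] * b[1])
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-reflection padding and
#' steady-state initial conditions, eliminating phase distortion and squaring
#' the magnitude response.
#'
#' @param b,a transfer-function coefficients.
#' @param x numeric series.
#' @return filtered series, same length as `x`.
#' @export
filtfilt <- function(b, a, x) {
  n <- length(x)
  padlen <- min(3 * max(length(a), length(b)), n - 1)
  if (n <= 2) return(x * 0)
  ext <- c(2 * x[1] - x[seq(padlen + 1, 2)],
           x,
           2 * x[n] - x[seq(n - 1, n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- lfilter(b, a, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + n)]
}

#' Band-pass a series with a zero-phase Butterworth filter
#'
#' If the requested upper edge reaches the Nyquist frequency the band is
#' truncated at 95% of Nyquist with a warning.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @param order Butterworth prototype order.
#' @return filtered series.
#' @export
bandpass <- function(x, fs, low, high, order = 4) {
  nyq <- fs / 2
  if (high >= nyq) {
    warnf("band edge %g Hz >= Nyquist (%g Hz); truncating band", high, nyq)
    high <- 0.95 * nyq
  }
  if (low >= high) stopf("degenerate band after truncation: [%g, %g] Hz", low, high)
  f <- butter_bandpass(order, low, high, fs)
  filtfilt(f$b, f$a, x)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with polynomial-fit handling of
#' the edges (each end is fitted once over the first/last frame and the fit is
#' evaluated at the edge samples), so polynomials up to `degree` are
#' reproduced exactly everywhere.
#'
#' @param y numeric series.
#' @param frame odd window length in samples, `> degree + 1`.
#' @param degree polynomial order (default 3).
#' @return smoothed series.
#' @export
savgol <- function(y, frame, degree = 3) {
  if (frame %% 2 != 1 || frame <= degree + 1) {
    stopf("frame must be odd and > degree + 1 (got %d)", frame)
  }
  n <- length(y)
  if (frame > n) stopf("frame (%d) larger than series (%d)", frame, n)
  h <- (frame - 1) / 2
  V <- outer(seq(-h, h), 0:degree, `^`)
  # smoothing kernel = row of the projection hat matrix at the window centre
  kern <- (V %*% solve(crossprod(V), t(V)))[h + 1, ]
  out <- stats::filter(y, rev(kern), sides = 2)
  out <- as.numeric(out)
  # edges: evaluate the polynomial fitted to the first/last frame
  Vh <- V %*% solve(crossprod(V), t(V))
  out[1:h] <- (Vh %*% y[1:frame])[1:h]
  out[(n - h + 1):n] <- (Vh %*% y[(n - frame + 1):n])[(h + 2):frame]
  out
}
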