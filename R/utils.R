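#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx quantile median sd var cor fft rnorm runif rpois
#'   setNames complete.cases lm coef wilcox.test rexp qnorm
#' @importFrom utils head tail modifyList write.table read.table
NULL

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Analytic signal via the frequency-domain Hilbert construction
#'
#' Returns `x + i * H(x)` where `H` is the Hilbert transform, computed by
#' zeroing negative frequencies of the FFT (doubling positive ones).
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n0 <- length(x)
  m <- stats::nextn(n0, c(2, 3, 5))
  if (m > n0) {
    # reflect-pad to an FFT-friendly length, truncate afterwards
    pad <- rev(x)[seq_len(m - n0)]
    return(analytic_signal(c(x, pad))[seq_len(n0)])
  }
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Segment-averaged periodogram with Hann-tapered windows.
#'
#' @param x signal.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return data.frame with columns `freq` (Hz) and `power`.
#' @export
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  nwin <- min(length(x), round(window_s * fs))
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nwin) / (nwin + 1)))  # Hann
  norm <- sum(w^2) * fs
  nf <- floor(nwin / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nwin - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(stats::fft(seg))^2 / norm
    acc <- acc + P[seq_len(nf)]
  }
  pw <- acc / length(starts)
  # one-sided: double everything but DC (and Nyquist for even nwin)
  if (nwin %% 2 == 0) pw[2:(nf - 1L)] <- 2 * pw[2:(nf - 1L)] else pw[2:nf] <- 2 * pw[2:nf]
  data.frame(freq = (seq_len(nf) - 1) * fs / nwin, power = pw)
}

# Gaussian-kernel smoothing of a regularly sampled vector; sigma in samples.
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2))[(half + 1):(half + n)]
}

# Centered moving average over `width` samples (odd-ified), edge-padded;
# O(n) via cumulative sums.
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L) return(x)
  half <- (width - 1L) / 2L
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  cs <- cumsum(c(0, xp))
  (cs[(width + 1):(width + n)] - cs[1:n]) / width
}

# Logical run-length intervals: start/end indices of TRUE runs.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Circularly shift a vector by k (positive = to the right).
circ_shift <- function(x, k) {
  n <- length(x)
  if (n == 0) return(x)
  k <- ((k %% n) + n) %% n
  if (k == 0) x else c(x[(n - k + 1):n], x[1:(n - k)])
}

# Overlap (s) between interval [a1,a2) and each row of cbind(b1,b2).
interval_overlap <- function(a1, a2, b1, b2) {
  pmax(0, pmin(a2, b2) - pmax(a1, b1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
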