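# Shared internal helpers: classed errors, framing, small DSP utilities.

.err <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "phonoPD_error")))
}

# Frame start indices for a signal of length n (samples), 1-based.
.frameStarts <- function(n, frameLen, hop) {
  if (n < frameLen) return(integer(0))
  seq(1L, n - frameLen + 1L, by = hop)
}

.rmsDb <- function(x) {
  r <- sqrt(mean(x^2))
  if (r <= 0) -Inf else 20 * log10(r)
}

# Normalized autocorrelation (biased) up to maxLag; returns vector r[1..maxLag]
# with r normalized by lag-0 energy; mean removed first.
.normAcf <- function(x, maxLag) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- stats::nextn(2L * n, 2L)
  X <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(Mod(X)^2, inverse = TRUE)) / nfft
  if (ac[1] <= 0) return(rep(0, maxLag))
  ac[seq(2L, maxLag + 1L)] / ac[1]
}

# Quadratic (parabolic) interpolation around a discrete peak at index i of y.
# Returns list(pos, val) with fractional position offset in [-0.5, 0.5].
.parabolicPeak <- function(y, i) {
  if (i <= 1L || i >= length(y)) return(list(pos = i, val = y[i]))
  a <- y[i - 1L]; b <- y[i]; c <- y[i + 1L]
  den <- a - 2 * b + c
  if (abs(den) < 1e-30) return(list(pos = i, val = b))
  d <- 0.5 * (a - c) / den
  d <- max(-0.5, min(0.5, d))
  list(pos = i + d, val = b - 0.25 * (a - c) * d)
}

# Linear-prediction coefficients by the autocorrelation (Levinson-Durbin)
# method. Returns a[1..order] such that x[n] ~ sum a[k] x[n-k].
.lpc <- function(x, order) {
  x <- x - mean(x)
  n <- length(x)
  r <- as.vector(stats::acf(x, lag.max = order, type = "covariance",
                            plot = FALSE, demean = FALSE)$acf)
  if (r[1] <= 0) return(rep(0, order))
  a <- numeric(order)
  e <- r[1]
  for (i in seq_len(order)) {
    k <- (r[i + 1] - sum(a[seq_len(i - 1)] * r[i:2])) / e
    if (!is.finite(k)) return(rep(0, order))
    a_new <- a
    a_new[i] <- k
    if (i > 1) a_new[seq_len(i - 1)] <- a[seq_len(i - 1)] - k * a[(i - 1):1]
    a <- a_new
    e <- e * (1 - k^2)
    if (e <= 0) break
  }
  a
}

# Inverse-filter x by LPC coefficients a (prediction residual).
.lpcResidual <- function(x, a) {
  as.vector(stats::filter(x, c(1, -a), method = "convolution", sides = 1))
}

# Hilbert amplitude envelope via the analytic signal.
.envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Deterministic per-iteration seed derived from a master seed (kept < 2^31).
.iterSeed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + i * 7L
}
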