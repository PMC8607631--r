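# Nonlinear-dynamics and information-theoretic measures of the voiced
# second. Heavy recurrences and pairwise sums run in compiled code
# (src/nonlinear.cpp); signals are analyzed at 22.05 kHz where state-space
# embedding is involved to bound pairwise-distance cost.

.downsampleHalf <- function(x, fs) {
  if (fs <= 22050) return(list(x = x, fs = fs))
  list(x = as.numeric(signal::decimate(x, 2L)), fs = fs / 2)
}

#' Recurrence period density entropy
#'
#' Time-delay embedding (default m = 4, tau = 35 samples at 22.05 kHz,
#' eps = 0.12 signal sd); for each embedded point the first return time to
#' its eps-ball after leaving it is recorded, and the normalized entropy of
#' the return-time distribution, `-sum p ln p / ln(Tmax)`, is returned.
#'
#' @param x numeric signal or a [Waveform-class] (waveforms are downsampled
#'   to 22.05 kHz first).
#' @param m embedding dimension.
#' @param tau embedding delay in samples.
#' @param epsFrac neighborhood radius as a fraction of the signal sd.
#' @return RPDE in \[0, 1\], or `NA` if no recurrences are found.
#' @export
rpde <- function(x, m = 4L, tau = 35L, epsFrac = 0.12) {
  if (is(x, "Waveform")) x <- .downsampleHalf(samples(x), sampleRate(x))$x
  s <- stats::sd(x)
  if (s <= 0) return(NA_real_)
  rets <- .rpde_returns(as.numeric(x), as.integer(m), as.integer(tau), epsFrac * s)
  if (length(rets) == 0) return(NA_real_)
  tmax <- max(rets)
  if (tmax < 2) return(0)
  p <- tabulate(rets, nbins = tmax)
  p <- p[p > 0] / sum(p)
  min(1, max(0, -sum(p * log(p)) / log(tmax)))
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Correlation sums over a log-spaced radius grid with a Theiler exclusion
#' window; D2 is the least-squares slope of `log C(r)` against `log r` over
#' the central scaling region (radii between the 10th and 50th percentile of
#' pairwise embedded distances).
#'
#' @param x numeric signal or a [Waveform-class].
#' @param m embedding dimension.
#' @param tau embedding delay in samples.
#' @param theiler Theiler window in samples (default: one mean period proxy,
#'   `tau * m`).
#' @param maxPoints cap on embedded points entering the pairwise sums.
#' @return the correlation dimension estimate, or `NA` for degenerate input.
#' @export
correlationDimension <- function(x, m = 4L, tau = 35L, theiler = NULL,
                                 maxPoints = 1500L) {
  if (is(x, "Waveform")) x <- .downsampleHalf(samples(x), sampleRate(x))$x
  if (stats::sd(x) <= 0) return(NA_real_)
  if (is.null(theiler)) theiler <- as.integer(tau) * as.integer(m)
  d <- .embed_pairdist(as.numeric(x), as.integer(m), as.integer(tau),
                       as.integer(theiler), as.integer(maxPoints))
  d <- d[d > 0]
  if (length(d) < 100) return(NA_real_)
  qs <- stats::quantile(d, c(0.10, 0.50), type = 7)
  rGrid <- exp(seq(log(qs[1]), log(qs[2]), length.out = 12))
  C <- vapply(rGrid, function(r) mean(d < r), 0)
  keep <- C > 0
  if (sum(keep) < 3) return(NA_real_)
  unname(stats::lm.fit(cbind(1, log(rGrid[keep])), log(C[keep]))$coefficients[2])
}

#' Pitch period entropy
#'
#' The per-cycle pitch sequence is mapped to a log (semitone-like) scale
#' relative to its median, whitened by an order-2 autoregressive filter fit
#' by least squares, and the normalized entropy of the residual histogram
#' over \[-0.5, 0.5\] in 30 bins is returned. Transposition invariant by
#' construction.
#'
#' @param f0Track numeric vector of per-cycle/frame pitch values (Hz).
#' @param bins histogram bin count.
#' @return PPE in \[0, 1\].
#' @export
ppe <- function(f0Track, bins = 30L) {
  if (length(f0Track) < 50)
    .err("phonoPD_insufficient_data_error",
         "need >= 50 pitch frames, got %d", length(f0Track))
  p <- log(f0Track / stats::median(f0Track))
  n <- length(p)
  y <- p[3:n]; X <- cbind(p[2:(n - 1)], p[1:(n - 2)])
  # order-2 AR whitening; fall back to raw deviations for degenerate tracks
  res <- tryCatch({
    cf <- stats::lm.fit(X, y)$coefficients
    cf[!is.finite(cf)] <- 0
    y - X %*% cf
  }, error = function(e) p)
  res <- pmax(-0.5, pmin(0.5, as.numeric(res)))
  h <- tabulate(pmin(bins, pmax(1, floor((res + 0.5) * bins) + 1)), nbins = bins)
  q <- h[h > 0] / sum(h)
  max(0, min(1, -sum(q * log(q)) / log(bins)))
}

#' Hurst exponent by detrended fluctuation analysis
#'
#' Order-1 DFA: the cumulative profile is split into non-overlapping windows
#' of log-spaced sizes 16 to length/8, linearly detrended per window, and
#' the slope of `log F(n)` against `log n` is the Hurst exponent.
#'
#' @param x numeric signal (length >= 1024) or a [Waveform-class].
#' @return the DFA exponent, or `NA` for a constant signal.
#' @export
hurstDfa <- function(x) {
  if (is(x, "Waveform")) x <- samples(x)
  if (length(x) < 1024) .err("phonoPD_insufficient_data_error", "need >= 1024 samples")
  if (stats::sd(x) <= 0) return(NA_real_)
  f <- .dfaFluctuations(x, q = NULL)
  unname(stats::lm.fit(cbind(1, log(f$scales)), log(f$F))$coefficients[2])
}

# Shared DFA core. With q = NULL returns the standard (q = 2) fluctuation
# function; otherwise a matrix of F_q(scale) for multifractal analysis.
.dfaFluctuations <- function(x, q = NULL, minScale = 16L, order = 1L) {
  n <- length(x)
  prof <- cumsum(x - mean(x))
  scales <- unique(round(exp(seq(log(minScale), log(n / 8), length.out = 14))))
  segVar <- function(s) {
    nSeg <- n %/% s
    qr1 <- qr(cbind(1, seq_len(s)))
    # order-1 fit residual variance per segment, from both ends of the series
    M <- cbind(matrix(prof[seq_len(nSeg * s)], nrow = s),
               matrix(prof[(n - nSeg * s + 1):n], nrow = s))
    colMeans(qr.resid(qr1, M)^2)
  }
  if (is.null(q)) {
    Fv <- vapply(scales, function(s) sqrt(mean(segVar(s))), 0)
    return(list(scales = scales, F = Fv))
  }
  Fq <- matrix(NA_real_, length(scales), length(q))
  for (i in seq_along(scales)) {
    v <- segVar(scales[i])
    v <- pmax(v, 1e-300)
    for (j in seq_along(q)) {
      Fq[i, j] <- if (q[j] == 0) exp(0.5 * mean(log(v))) else mean(v^(q[j] / 2))^(1 / q[j])
    }
  }
  list(scales = scales, Fq = Fq)
}

#' Normalized two-symbol Lempel-Ziv complexity
#'
#' The signal is binarized at its median and parsed by the LZ76
#' exhaustive-history scheme; the word count `c(n)` is normalized as
#' `c(n) * log2(n) / n` and clipped to \[0, 1\].
#'
#' @param x numeric signal (length >= 64) or a [Waveform-class].
#' @return normalized LZ complexity in \[0, 1\].
#' @export
lz2 <- function(x) {
  if (is(x, "Waveform")) x <- samples(x)
  n <- length(x)
  if (n < 64) .err("phonoPD_insufficient_data_error", "need >= 64 samples")
  bits <- as.integer(x > stats::median(x))
  cN <- .lz76_count(bits)
  max(0, min(1, cN * log2(n) / n))
}

#' Permutation entropy
#'
#' Shannon entropy of the ordinal-pattern distribution over all length-`m`
#' delay windows, normalized by `ln(m!)`. Ties are broken by order of
#' occurrence (earlier sample ranks lower).
#'
#' @param x numeric signal or a [Waveform-class].
#' @param m pattern length.
#' @param tau delay between pattern elements (samples).
#' @return permutation entropy in \[0, 1\].
#' @export
permutationEntropy <- function(x, m = 3L, tau = 1L) {
  if (is(x, "Waveform")) x <- samples(x)
  n <- length(x)
  if (n <= m * tau) .err("phonoPD_insufficient_data_error", "signal too short for patterns")
  nWin <- n - (m - 1L) * tau
  cols <- vapply(seq_len(m) - 1L, function(k) x[(1:nWin) + k * tau], numeric(nWin))
  # within-window rank of element k (0-based), ties to the earlier element;
  # the rank vector is a permutation, encoded injectively in base m
  codes <- numeric(nWin)
  for (k in seq_len(m)) {
    rk <- numeric(nWin)
    for (j in seq_len(m)) {
      if (j == k) next
      rk <- rk + (cols[, j] < cols[, k] | (cols[, j] == cols[, k] & j < k))
    }
    codes <- codes + rk * m^(k - 1)
  }
  tab <- table(codes)
  p <- as.numeric(tab) / sum(tab)
  max(0, min(1, -sum(p * log(p)) / log(factorial(m))))
}

#' Normalized Shannon entropy of the amplitude histogram
#'
#' Histogram over `[-max|x|, max|x|]` with equal bins;
#' `-sum p log2 p / log2(bins)`. An all-zero signal returns 0 by convention.
#'
#' @param x numeric signal or a [Waveform-class].
#' @param bins histogram bin count.
#' @return entropy in \[0, 1\].
#' @export
shannonEntropy <- function(x, bins = 64L) {
  if (is(x, "Waveform")) x <- samples(x)
  a <- max(abs(x))
  if (a <= 0) return(0)
  idx <- pmin(bins, pmax(1, floor((x + a) / (2 * a) * bins) + 1))
  h <- tabulate(idx, nbins = bins)
  p <- h[h > 0] / sum(h)
  max(0, min(1, -sum(p * log2(p)) / log2(bins)))
}

#' First minimum of the auto mutual information (ms)
#'
#' Histogram-based (32 x 32 bins) mutual information between `x_t` and
#' `x_(t+tau)` for increasing lags; the lag of the first strict local minimum
#' is returned in milliseconds. A minimum at the very first lag counts; if no
#' minimum exists within range, `maxLagMs` is returned with attribute
#' `noMinimum = TRUE`.
#'
#' @param x numeric signal or a [Waveform-class] (rate taken from the object).
#' @param rateHz sample rate when `x` is a bare vector.
#' @param maxLagMs largest lag examined.
#' @param bins marginal histogram bin count.
#' @return lag of the first AMI minimum in ms.
#' @export
amiFirstMin <- function(x, rateHz = 44100, maxLagMs = 20, bins = 32L) {
  if (is(x, "Waveform")) { rateHz <- sampleRate(x); x <- samples(x) }
  if (length(x) < 2048) .err("phonoPD_insufficient_data_error", "need >= 2048 samples")
  maxLag <- max(2L, round(maxLagMs / 1000 * rateHz))
  rng <- range(x)
  if (diff(rng) <= 0) .err("phonoPD_insufficient_data_error", "constant signal")
  ix <- pmin(bins, pmax(1L, floor((x - rng[1]) / diff(rng) * bins) + 1L))
  n <- length(x)
  mi <- vapply(seq_len(maxLag), function(lag) {
    a <- ix[1:(n - lag)]; b <- ix[(1 + lag):n]
    joint <- tabulate(a + bins * (b - 1L), nbins = bins * bins)
    joint <- joint / sum(joint)
    pa <- tabulate(a, nbins = bins) / length(a)
    pb <- tabulate(b, nbins = bins) / length(b)
    nz <- joint > 0
    outerP <- as.vector(outer(pa, pb))
    sum(joint[nz] * log(joint[nz] / outerP[nz]))
  }, 0)
  # Structured signals need smoothing so histogram noise does not fake
  # minima on the declining MI curve; structureless (flat) MI profiles are
  # searched raw, where the first dip is genuinely the first minimum.
  # first prominent minimum: a running minimum is confirmed once the curve
  # rises above it by 15% of the MI range, so estimator wiggle on a declining
  # curve cannot fake a minimum while a flat (structureless) curve confirms
  # its first dip immediately
  delta <- 0.15 * diff(range(mi))
  best <- Inf
  bestIdx <- NA_integer_
  for (t in seq_len(maxLag)) {
    if (mi[t] < best) {
      best <- mi[t]
      bestIdx <- t
    } else if (mi[t] > best + delta) {
      return(bestIdx / rateHz * 1000)
    }
  }
  out <- maxLagMs
  attr(out, "noMinimum") <- TRUE
  out
}

#' First zero crossing of the autocorrelation (ms)
#'
#' First lag at which the biased normalized autocorrelation crosses zero,
#' linearly interpolated between lag samples, in milliseconds.
#'
#' @param x numeric signal or a [Waveform-class].
#' @param rateHz sample rate when `x` is a bare vector.
#' @param maxLagMs largest lag examined.
#' @return crossing lag in ms, or `NA` (flagged) if none within range.
#' @export
acfFirstZero <- function(x, rateHz = 44100, maxLagMs = 50) {
  if (is(x, "Waveform")) { rateHz <- sampleRate(x); x <- samples(x) }
  if (stats::sd(x) <= 0) .err("phonoPD_insufficient_data_error", "constant signal")
  maxLag <- max(2L, round(maxLagMs / 1000 * rateHz))
  maxLag <- min(maxLag, length(x) - 1L)
  r <- c(1, .normAcf(x, maxLag))
  below <- which(r <= 0)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]  # r index i corresponds to lag i-1
  lagHi <- i - 1; lagLo <- i - 2
  frac <- r[i - 1] / (r[i - 1] - r[i])
  (lagLo + frac) / rateHz * 1000
}

#' Multifractal spectrum width (MFDFA)
#'
#' Multifractal detrended fluctuation analysis with order-1 detrending over
#' log-spaced scales 16 to length/8 and moments `q` in -5..5 (log-mean for
#' q = 0): generalized Hurst exponents `h(q)` by per-q regression, singularity
#' strengths `alpha(q) = h(q) + q h'(q)` by finite differences, and the
#' spectrum width `max(alpha) - min(alpha)`.
#'
#' @param x numeric series (length >= 4096) or a [Waveform-class].
#' @param qGrid moment orders.
#' @return spectrum width (>= 0), or `NA` when scaling is degenerate
#'   (regression R^2 < 0.9 for more than half the q values).
#' @export
mfsw <- function(x, qGrid = c(-5:-1, 0, 1:5)) {
  if (is(x, "Waveform")) x <- .downsampleHalf(samples(x), sampleRate(x))$x
  if (length(x) < 4096) .err("phonoPD_insufficient_data_error", "need >= 4096 samples")
  if (stats::sd(x) <= 0) return(NA_real_)
  f <- .dfaFluctuations(x, q = qGrid)
  logS <- log2(f$scales)
  h <- r2 <- numeric(length(qGrid))
  for (j in seq_along(qGrid)) {
    y <- log2(f$Fq[, j])
    fit <- stats::lm.fit(cbind(1, logS), y)
    h[j] <- fit$coefficients[2]
    r2[j] <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  }
  if (mean(r2 < 0.9) > 0.5) return(NA_real_)
  # alpha = h + q h'(q), h' by central finite differences
  dh <- numeric(length(qGrid))
  dh[1] <- (h[2] - h[1]) / (qGrid[2] - qGrid[1])
  nq <- length(qGrid)
  dh[nq] <- (h[nq] - h[nq - 1]) / (qGrid[nq] - qGrid[nq - 1])
  for (j in 2:(nq - 1)) dh[j] <- (h[j + 1] - h[j - 1]) / (qGrid[j + 1] - qGrid[j - 1])
  alpha <- h + qGrid * dh
  max(0, max(alpha) - min(alpha))
}

#' Extract all nonlinear features from a voiced second
#'
#' Runs every nonlinear extractor on the (downsampled) signal, using the
#' per-cycle pitch track from `cycles` for the pitch period entropy. Failed
#' extractors yield `NA`.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @param cycles optional [CycleSeries-class] (detected on demand if absent).
#' @return named numeric vector of 10 features.
#' @export
extractNonlinearFeatures <- function(w, cycles = NULL) {
  ds <- .downsampleHalf(samples(w), sampleRate(w))
  grab <- function(f) tryCatch(as.numeric(f)[1], error = function(e) NA_real_)
  if (is.null(cycles)) cycles <- tryCatch(detectCycles(w), error = function(e) NULL)
  f0Track <- if (!is.null(cycles)) 1 / cyclePeriods(cycles) else numeric(0)
  c(rpde = grab(rpde(ds$x)),
    d2 = grab(correlationDimension(ds$x)),
    ppe = grab(ppe(f0Track)),
    hurst = grab(hurstDfa(ds$x)),
    lz2 = grab(lz2(ds$x)),
    perm_entropy = grab(permutationEntropy(ds$x)),
    shannon_entropy = grab(shannonEntropy(ds$x)),
    ami_first_min_ms = grab(amiFirstMin(ds$x, rateHz = ds$fs)),
    mfsw = grab(mfsw(ds$x)),
    acf_first_zero_ms = grab(acfFirstZero(ds$x, rateHz = ds$fs)))
}
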