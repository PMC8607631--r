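# Pitch-synchronous, noise, cepstral, glottal and spectral features extracted
# from a trimmed one-second voiced segment.

#' Detect glottal cycles
#'
#' Estimates the mean fundamental period from the global normalized
#' autocorrelation peak in the \[1/f0Max, 1/f0Min\] lag band, then places
#' cycle marks by matched peak picking constrained to +/- 30% of the running
#' period, with parabolic sub-sample refinement of both peak position and
#' amplitude. Peaks are picked on the linear-prediction residual, whose
#' impulses mark the glottal closure instants free of formant ringing; for
#' near-perfectly predictable signals (a pure tone leaves no residual) the
#' waveform itself is used.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @param f0MinHz,f0MaxHz fundamental-frequency search band (Hz).
#' @return a [CycleSeries-class].
#' @export
detectCycles <- function(w, f0MinHz = 50, f0MaxHz = 500) {
  x <- samples(w)
  fs <- sampleRate(w)
  lagMin <- max(2L, floor(fs / f0MaxHz))
  lagMax <- ceiling(fs / f0MinHz)
  if (lagMax >= length(x)) .err("phonoPD_unvoiced_error", "signal too short for pitch analysis")
  r <- .normAcf(x, lagMax)
  band <- lagMin:lagMax
  iPk <- band[which.max(r[band])]
  if (r[iPk] <= 0.3)
    .err("phonoPD_unvoiced_error",
         "no periodicity found (max normalized ACF %.2f <= 0.3 in search band)", r[iPk])
  T0 <- .parabolicPeak(r, iPk)$pos

  # glottal-closure track: LPC residual impulses; waveform fallback for
  # signals the predictor explains almost perfectly (pure tones)
  a <- .lpc(x, 2L + round(fs / 1000))
  res <- .lpcResidual(x, a)
  res[!is.finite(res)] <- 0
  kurt <- if (stats::sd(res) > 0) mean(res^4) / mean(res^2)^2 else 0
  impulsive <- stats::sd(res) > 1e-6 * stats::sd(x) && kurt > 3.5
  p <- if (impulsive) {
    # short moving average of the rectified residual: keeps closure-instant
    # peaks sharp while suppressing single-sample noise spikes
    sm <- max(3L, round(0.0005 * fs))
    env <- as.numeric(stats::filter(abs(res), rep(1 / sm, sm), sides = 2))
    env[is.na(env)] <- 0
    env
  } else {
    pol <- if (abs(max(x)) >= abs(min(x))) 1 else -1
    pol * x
  }
  ref <- which.max(p)
  findPeak <- function(lo, hi) {
    lo <- max(1L, floor(lo)); hi <- min(length(p), ceiling(hi))
    if (hi - lo < 2L) return(NULL)
    seg <- p[lo:hi]
    pk <- .parabolicPeak(seg, which.max(seg))
    list(pos = lo - 1 + pk$pos, val = pk$val)
  }
  onsets <- numeric(0); vals <- numeric(0)
  # the running period may drift only 25% from the global estimate, so noise
  # peaks cannot walk the tracker onto a wrong octave
  Tlo <- max(fs / f0MaxHz, 0.75 * T0)
  Thi <- min(fs / f0MinHz, 1.25 * T0)
  # forward pass: search windows kept fully inside the signal
  pos <- ref; Trun <- T0
  while (pos + 1.3 * Trun <= length(p)) {
    nxt <- findPeak(pos + 0.7 * Trun, pos + 1.3 * Trun)
    if (is.null(nxt)) break
    onsets <- c(onsets, nxt$pos); vals <- c(vals, nxt$val)
    Trun <- max(Tlo, min(Thi, nxt$pos - pos))
    pos <- nxt$pos
  }
  # backward pass
  posB <- ref; Trun <- T0
  while (posB - 1.3 * Trun >= 1) {
    prv <- findPeak(posB - 1.3 * Trun, posB - 0.7 * Trun)
    if (is.null(prv)) break
    onsets <- c(prv$pos, onsets); vals <- c(prv$val, vals)
    Trun <- max(Tlo, min(Thi, posB - prv$pos))
    posB <- prv$pos
  }
  refPk <- .parabolicPeak(p, ref)
  onsets <- c(onsets, refPk$pos); vals <- c(vals, refPk$val)
  o <- order(onsets)
  onsets <- onsets[o]; vals <- vals[o]
  # drop spurious low-amplitude edge marks (no glottal event in the tail)
  keep <- vals >= 0.2 * stats::median(vals)
  onsets <- onsets[keep]; vals <- vals[keep]
  if (length(onsets) < 3) .err("phonoPD_unvoiced_error", "fewer than 3 cycle marks found")
  periods <- diff(onsets) / fs
  ok <- periods >= 1 / f0MaxHz & periods <= 1 / f0MinHz
  # amplitude of cycle i = refined peak magnitude at its left mark
  amps <- abs(vals[-length(vals)])
  new("CycleSeries", onsets = onsets, periodsS = periods[ok], peakAmps = amps[ok],
      openS = numeric(0), closedS = numeric(0), rateHz = as.integer(fs))
}

#' Local jitter (percent)
#'
#' `100 * mean(|T[i+1] - T[i]|) / mean(T)` over consecutive cycle periods.
#'
#' @param c a [CycleSeries-class] (or any object with [cyclePeriods()]).
#' @return jitter in percent.
#' @export
jitterLocal <- function(c) {
  p <- cyclePeriods(c)
  if (length(p) < 2) .err("phonoPD_insufficient_cycles_error", "need >= 2 cycles for jitter")
  100 * mean(abs(diff(p))) / mean(p)
}

#' Local shimmer (percent)
#'
#' `100 * mean(|A[i+1] - A[i]|) / mean(A)` over consecutive cycle peak
#' amplitudes.
#'
#' @param c a [CycleSeries-class] (or any object with [cycleAmps()]).
#' @return shimmer in percent.
#' @export
shimmerLocal <- function(c) {
  a <- cycleAmps(c)
  if (length(a) < 2) .err("phonoPD_insufficient_cycles_error", "need >= 2 cycles for shimmer")
  100 * mean(abs(diff(a))) / mean(a)
}

#' Harmonics-to-noise ratio (dB)
#'
#' Frame-wise normalized-autocorrelation HNR: per 40 ms frame (10 ms hop) the
#' normalized ACF is evaluated near the local period lag; with `r` the peak
#' value (clipped to \[0.001, 0.999\]), frame HNR is `10*log10(r/(1-r))` and
#' the mean over frames is returned.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @param c the [CycleSeries-class] detected on `w`.
#' @return HNR in dB (ceiling about 30 dB from the clipping).
#' @export
hnrDb <- function(w, c) {
  x <- samples(w)
  fs <- sampleRate(w)
  frameLen <- round(0.040 * fs)
  hop <- round(0.010 * fs)
  starts <- .frameStarts(length(x), frameLen, hop)
  # search a 10% band around the mean period: individual cycle marks are
  # noisy at low HNR, the mean period is not
  lagC <- round(mean(cyclePeriods(c)) * fs)
  lo <- max(2L, floor(0.9 * lagC)); hi <- min(frameLen - 2L, ceiling(1.1 * lagC))
  vals <- vapply(starts, function(s) {
    seg <- x[s:(s + frameLen - 1L)]
    r <- max(vapply(lo:hi, function(l) .overlapCorr(seg, l), 0))
    r <- max(0.001, min(0.999, r))
    10 * log10(r / (1 - r))
  }, 0)
  mean(vals)
}

# Pearson correlation between a frame and its lagged self over the
# overlapping part; unlike the biased ACF it reaches 1 for periodic frames.
.overlapCorr <- function(seg, lag) {
  n <- length(seg)
  a <- seg[1:(n - lag)]; b <- seg[(1 + lag):n]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den <= 0) return(0)
  sum(a * b) / den
}

#' Cepstral peak prominence (dB)
#'
#' Per 40 ms Hamming frame (20 ms hop): the real cepstrum of the dB log
#' magnitude spectrum is computed, its peak located in the 2-20 ms quefrency
#' band, and a least-squares line fitted to the cepstrum over that band;
#' frame CPP is the peak height above the line, and the mean over frames is
#' returned. Gain changes only offset the excluded zero-quefrency bin, so the
#' measure is gain invariant.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @return CPP in dB.
#' @export
cppDb <- function(w) {
  x <- samples(w)
  fs <- sampleRate(w)
  frameLen <- round(0.040 * fs)
  hop <- round(0.020 * fs)
  win <- .hammingWin(frameLen)
  qLo <- round(0.002 * fs); qHi <- round(0.020 * fs)
  starts <- .frameStarts(length(x), frameLen, hop)
  nfft <- stats::nextn(frameLen, 2)
  vals <- vapply(starts, function(s) {
    seg <- x[s:(s + frameLen - 1L)] * win
    spec <- Mod(stats::fft(c(seg, rep(0, nfft - frameLen))))
    logspec <- 20 * log10(pmax(spec, max(spec) * 1e-12))
    # cepstral magnitude in dB: prominence is then itself a dB quantity
    cep <- Mod(stats::fft(logspec, inverse = TRUE)) / nfft
    cepDb <- 20 * log10(pmax(cep, 1e-12))
    band <- qLo:min(qHi, nfft / 2)
    iPk <- band[which.max(cepDb[band])]
    fitLine <- stats::lm.fit(cbind(1, band), cepDb[band])$coefficients
    cepDb[iPk] - (fitLine[1] + fitLine[2] * iPk)
  }, 0)
  mean(vals)
}

.hammingWin <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Glottal-to-noise excitation ratio
#'
#' The signal is downsampled to 10 kHz and inverse-filtered by frame-wise
#' linear prediction (order 13, 30 ms frames); Hilbert envelopes of the
#' residual band-passed in 1000 Hz-wide bands centered every 500 Hz from
#' 500 to 4500 Hz are cross-correlated (lags up to +/- 0.3 ms) for band pairs
#' whose centers differ by more than 500 Hz; GNE is the maximum correlation,
#' averaged over frames.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @return GNE in \[0, 1\].
#' @export
gne <- function(w) {
  fsT <- 10000
  x <- .resampleTo(samples(w), sampleRate(w), fsT)
  frameLen <- round(0.030 * fsT)
  hop <- round(0.015 * fsT)
  centers <- seq(500, 4500, by = 500)
  halfBw <- 500
  maxLag <- round(0.0003 * fsT)
  pairs <- which(outer(centers, centers, function(a, b) b - a) > halfBw + 1, arr.ind = TRUE)
  starts <- .frameStarts(length(x), frameLen, hop)
  vals <- vapply(starts, function(s) {
    seg <- x[s:(s + frameLen - 1L)]
    a <- .lpc(seg, 13)
    res <- .lpcResidual(seg, a)
    res[!is.finite(res)] <- 0
    n <- length(res)
    RES <- stats::fft(res)
    freqs <- (seq_len(n) - 1) / n * fsT
    env <- lapply(centers, function(fc) {
      keep <- freqs >= fc - halfBw & freqs <= fc + halfBw  # analytic: positive band only
      Mod(stats::fft(RES * keep, inverse = TRUE) / n)
    })
    best <- 0
    for (k in seq_len(nrow(pairs))) {
      e1 <- env[[pairs[k, 1]]]; e2 <- env[[pairs[k, 2]]]
      e1 <- e1 - mean(e1); e2 <- e2 - mean(e2)
      den <- sqrt(sum(e1^2) * sum(e2^2))
      if (den <= 0) next
      for (lag in -maxLag:maxLag) {
        if (lag >= 0) {
          cc <- sum(e1[1:(n - lag)] * e2[(1 + lag):n]) / den
        } else {
          cc <- sum(e1[(1 - lag):n] * e2[1:(n + lag)]) / den
        }
        if (cc > best) best <- cc
      }
    }
    best
  }, 0)
  max(0, min(1, mean(vals)))
}

.resampleTo <- function(x, fsFrom, fsTo) {
  if (fsFrom == fsTo) return(x)
  g <- .gcd(as.integer(fsTo), as.integer(fsFrom))
  as.numeric(signal::resample(x, as.integer(fsTo) / g, as.integer(fsFrom) / g))
}

#' Zero crossing rate (crossings per second)
#'
#' Sign changes between consecutive samples (zeros attached to the preceding
#' sign) divided by the duration in seconds.
#'
#' @param w a [Waveform-class].
#' @return crossings per second.
#' @export
zcr <- function(w) {
  x <- samples(w)
  s <- sign(x)
  # attach zeros to the preceding sign
  for (i in which(s == 0)) s[i] <- if (i > 1) s[i - 1] else 1
  if (all(s == 0)) return(0)
  sum(diff(s) != 0) / durationS(w)
}

#' Glottal quotient features
#'
#' Estimates the glottal flow by iterative adaptive inverse filtering (two
#' LPC passes with lip-radiation integration), splits each detected cycle
#' into an open phase (flow above 50% of the cycle range, longest contiguous
#' run) and a closed phase, and returns three dimensionless dispersion
#' statistics: `gq_prc5_95` (5th-95th percentile range of periods over mean
#' period) and the open/closed phase duration sds over mean period.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @param c the [CycleSeries-class] detected on `w`.
#' @return named numeric `c(gq_prc5_95, gq_std_cycle_open, gq_std_cycle_closed)`;
#'   the phase statistics are `NA` when glottal analysis degenerates (empty
#'   open phase in more than half the cycles).
#' @export
glottalQuotients <- function(w, c) {
  x <- samples(w)
  fs <- sampleRate(w)
  p <- cyclePeriods(c)
  meanT <- mean(p)
  prc <- unname(stats::quantile(p, c(0.05, 0.95), type = 7))
  gqPrc <- (prc[2] - prc[1]) / meanT

  vtOrder <- 2L + round(fs / 1000)
  integrate <- function(v) {
    v[!is.finite(v)] <- 0
    stats::filter(v, 0.99, method = "recursive")
  }
  # pass 1: remove a first-order glottal tilt estimate, model the tract
  g1 <- .lpc(x, 1)
  y1 <- .lpcResidual(x, g1); y1[!is.finite(y1)] <- 0
  vt1 <- .lpc(y1, vtOrder)
  flow1 <- as.numeric(integrate(.lpcResidual(x, vt1)))
  # pass 2: refine the source model (order 4), re-estimate the tract
  g2 <- .lpc(flow1, 4)
  y2 <- .lpcResidual(x, g2); y2[!is.finite(y2)] <- 0
  vt2 <- .lpc(y2, vtOrder)
  flow <- as.numeric(integrate(.lpcResidual(x, vt2)))

  # light smoothing so LPC ripple does not split the open-phase run
  sm <- max(3L, round(0.0005 * fs))
  flow <- as.numeric(stats::filter(flow, rep(1 / sm, sm), sides = 2))
  onsets <- cycleOnsets(c)
  openS <- closedS <- rep(NA_real_, length(p))
  for (i in seq_along(p)) {
    lo <- max(1L, floor(onsets[i])); hi <- min(length(flow), floor(onsets[i + 1]) - 1L)
    if (hi - lo < 4L || anyNA(flow[lo:hi])) next
    seg <- flow[lo:hi]
    rng <- range(seg)
    if (diff(rng) <= 0) next
    above <- seg > rng[1] + 0.5 * diff(rng)
    if (!any(above)) next
    runs <- rle(above)
    lens <- runs$lengths[runs$values]
    openS[i] <- max(lens) / fs
    closedS[i] <- (length(seg) - max(lens)) / fs
  }
  if (mean(is.na(openS)) > 0.5) {
    return(c(gq_prc5_95 = gqPrc, gq_std_cycle_open = NA_real_,
             gq_std_cycle_closed = NA_real_))
  }
  c(gq_prc5_95 = gqPrc,
    gq_std_cycle_open = stats::sd(openS, na.rm = TRUE) / meanT,
    gq_std_cycle_closed = stats::sd(closedS, na.rm = TRUE) / meanT)
}

#' Mel-frequency cepstral coefficients 1-13
#'
#' 25 ms Hamming frames with 10 ms hop, 26 triangular mel filters spanning
#' 0 to Nyquist, log filterbank energies, DCT-II; coefficients 1-13 (the
#' gain-carrying 0th excluded) averaged over frames.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @param nFilters number of mel filters.
#' @return named numeric `mfcc_1` ... `mfcc_13`.
#' @export
mfcc13 <- function(w, nFilters = 26L) {
  x <- samples(w)
  fs <- sampleRate(w)
  frameLen <- round(0.025 * fs)
  hop <- round(0.010 * fs)
  win <- .hammingWin(frameLen)
  nfft <- stats::nextn(frameLen, 2)
  nBins <- nfft / 2 + 1
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(0), mel(fs / 2), length.out = nFilters + 2))
  binFreq <- (seq_len(nBins) - 1) * fs / nfft
  fb <- matrix(0, nFilters, nBins)
  for (k in seq_len(nFilters)) {
    lo <- edges[k]; mid <- edges[k + 1]; hi <- edges[k + 2]
    up <- (binFreq - lo) / (mid - lo)
    down <- (hi - binFreq) / (hi - mid)
    fb[k, ] <- pmax(0, pmin(up, down))
  }
  starts <- .frameStarts(length(x), frameLen, hop)
  dctMat <- .dct2Matrix(13, nFilters)
  acc <- numeric(13)
  for (s in starts) {
    seg <- x[s:(s + frameLen - 1L)] * win
    pspec <- Mod(stats::fft(c(seg, rep(0, nfft - frameLen))))[seq_len(nBins)]^2
    fe <- as.vector(fb %*% pspec)
    fe <- pmax(fe, max(fe, .Machine$double.xmin) * 1e-12)  # gain-relative floor
    acc <- acc + as.vector(dctMat %*% log(fe))
  }
  out <- acc / length(starts)
  names(out) <- paste0("mfcc_", 1:13)
  out
}

# DCT-II rows 1..nCoef (0th excluded) for input length n.
.dct2Matrix <- function(nCoef, n) {
  k <- seq_len(nCoef)
  j <- seq_len(n) - 0.5
  outer(k, j, function(k, j) cos(pi * k * j / n)) * sqrt(2 / n)
}

#' Extract all acoustic features from a voiced second
#'
#' Runs cycle detection and every acoustic extractor, returning the named
#' 22-component acoustic block (jitter, shimmer, CPP, HNR, GNE, ZCR, three
#' glottal quotients, MFCC 1-13). Extractors that fail return `NA` for their
#' components rather than aborting the row.
#'
#' @param w a trimmed voiced [Waveform-class].
#' @return named numeric vector of 22 features.
#' @export
extractAcousticFeatures <- function(w) {
  out <- c(jitter_pct = NA_real_, shimmer_pct = NA_real_, cpp_db = NA_real_,
           hnr_db = NA_real_, gne = NA_real_, zcr_per_s = NA_real_,
           gq_prc5_95 = NA_real_, gq_std_cycle_open = NA_real_,
           gq_std_cycle_closed = NA_real_,
           stats::setNames(rep(NA_real_, 13), paste0("mfcc_", 1:13)))
  cyc <- tryCatch(detectCycles(w), error = function(e) NULL)
  if (!is.null(cyc)) {
    out["jitter_pct"] <- tryCatch(jitterLocal(cyc), error = function(e) NA_real_)
    out["shimmer_pct"] <- tryCatch(shimmerLocal(cyc), error = function(e) NA_real_)
    out["hnr_db"] <- tryCatch(hnrDb(w, cyc), error = function(e) NA_real_)
    gq <- tryCatch(glottalQuotients(w, cyc), error = function(e)
      c(gq_prc5_95 = NA_real_, gq_std_cycle_open = NA_real_, gq_std_cycle_closed = NA_real_))
    out[names(gq)] <- gq
  }
  out["cpp_db"] <- tryCatch(cppDb(w), error = function(e) NA_real_)
  out["gne"] <- tryCatch(gne(w), error = function(e) NA_real_)
  out["zcr_per_s"] <- zcr(w)
  mf <- tryCatch(mfcc13(w), error = function(e)
    stats::setNames(rep(NA_real_, 13), paste0("mfcc_", 1:13)))
  out[names(mf)] <- mf
  out
}
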