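# Source-filter synthesis of sustained vowels with cycle-level ground truth,
# plus statistical cohort simulators used to exercise the selection and
# evaluation machinery.

# Rosenberg glottal flow pulse sampled over one period of `period` samples.
# Open quotient oq (fraction of the period the glottis is open), speed
# quotient sq = rising/falling duration ratio.
.rosenbergPulse <- function(period, oq = 0.6, sq = 2) {
  nOpen <- max(3L, round(oq * period))
  nRise <- max(2L, round(nOpen * sq / (sq + 1)))
  nFall <- max(1L, nOpen - nRise)
  rise <- 0.5 * (1 - cos(pi * seq_len(nRise) / nRise))
  fall <- cos(pi * seq_len(nFall) / (2 * nFall))
  pulse <- numeric(period)
  pulse[seq_len(nRise)] <- rise
  pulse[nRise + seq_len(min(nFall, period - nRise))] <-
    fall[seq_len(min(nFall, period - nRise))]
  pulse
}

# Cascade of second-order all-pole resonators (center/bandwidth in Hz).
.formantFilter <- function(x, formants, fs) {
  for (f in formants) {
    r <- exp(-pi * f[2] / fs)
    theta <- 2 * pi * f[1] / fs
    # unity gain at DC keeps amplitudes comparable across formant sets
    b <- 1 - 2 * r * cos(theta) + r^2
    x <- b * as.numeric(stats::filter(x, c(2 * r * cos(theta), -r^2),
                                      method = "recursive"))
  }
  x
}

#' Synthesize a sustained vowel with known cycle-level ground truth
#'
#' Source-filter synthesis: a Rosenberg glottal pulse train with per-cycle
#' period factors `1 + jitterPct/100 * z_i` and per-cycle gains
#' `1 + shimmerPct/100 * z'_i` (`z`, `z'` iid standard normal clipped at
#' +/- 3) is passed through a cascade of formant resonators and a
#' lip-radiation differentiator; white Gaussian noise, filtered the same way,
#' is added so the periodic-to-noise power ratio at the filter output equals
#' `hnrDb`. The result is peak-normalized to 0.9 and fully determined by
#' `seed`.
#'
#' @param f0Hz fundamental frequency in \[50, 500\] Hz.
#' @param durationS duration in seconds.
#' @param jitterPct,shimmerPct target cycle-to-cycle perturbations (percent).
#' @param hnrDb target harmonics-to-noise ratio in dB; `Inf` adds no noise.
#' @param formants list of `c(center_hz, bandwidth_hz)`; default /a/.
#' @param rateHz sample rate (>= 8000).
#' @param seed integer RNG seed.
#' @return `list(wave = Waveform, truth = SynthesisTruth)`.
#' @export
synthVowel <- function(f0Hz = 120, durationS = 1, jitterPct = 0, shimmerPct = 0,
                       hnrDb = Inf,
                       formants = list(c(700, 80), c(1220, 120), c(2600, 160)),
                       rateHz = 44100L, seed = 1L) {
  if (f0Hz < 50 || f0Hz > 500) .err("phonoPD_spec_error", "f0 must lie in [50, 500] Hz")
  if (durationS <= 0) .err("phonoPD_spec_error", "duration must be positive")
  if (rateHz < 8000) .err("phonoPD_spec_error", "rate must be >= 8000 Hz")
  if (jitterPct < 0 || shimmerPct < 0)
    .err("phonoPD_spec_error", "perturbations must be non-negative")
  set.seed(as.integer(seed))
  fs <- as.integer(rateHz)
  n <- round(durationS * fs)
  T0 <- fs / f0Hz
  nCycMax <- ceiling(n / T0 * (1 + 3 * jitterPct / 100)) + 2L
  zj <- pmax(-3, pmin(3, stats::rnorm(nCycMax)))
  zs <- pmax(-3, pmin(3, stats::rnorm(nCycMax)))
  periods <- round(T0 * (1 + jitterPct / 100 * zj))
  if (any(periods <= 0))
    .err("phonoPD_spec_error", "jitter so large that cycle periods become non-positive")
  amps <- 1 + shimmerPct / 100 * zs
  amps[amps < 0.01] <- 0.01

  onsets <- cumsum(c(1, periods))[seq_along(periods)]
  keep <- which(onsets + periods - 1 <= n)
  onsets <- onsets[keep]
  periods <- periods[keep]
  amps <- amps[keep]
  if (length(onsets) < 2)
    .err("phonoPD_spec_error", "duration too short for two glottal cycles")

  # fixed pulse shape sized from the nominal period: period perturbations are
  # absorbed by the closed phase, so glottal events track the cycle onsets
  pulse <- .rosenbergPulse(round(T0))
  src <- numeric(n + length(pulse))
  for (i in seq_along(onsets)) {
    idx <- onsets[i]:(onsets[i] + length(pulse) - 1)
    src[idx] <- src[idx] + pulse * amps[i]
  }
  src <- src[seq_len(n)]
  periodic <- .formantFilter(src, formants, fs)
  periodic <- c(0, diff(periodic))  # lip radiation

  noisePower <- 0
  out <- periodic
  if (is.finite(hnrDb)) {
    noise <- .formantFilter(stats::rnorm(n), formants, fs)
    noise <- c(0, diff(noise))
    pPer <- mean(periodic^2)
    targetNoise <- pPer / 10^(hnrDb / 10)
    noise <- noise * sqrt(targetNoise / mean(noise^2))
    noisePower <- targetNoise
    out <- periodic + noise
  }
  g <- 0.9 / max(abs(out))
  out <- out * g

  truth <- new("SynthesisTruth",
               cycleOnsets = as.integer(onsets),
               cyclePeriodsS = periods / fs,
               cycleAmps = amps,
               voicedRange = c(1L, as.integer(onsets[length(onsets)] +
                                                periods[length(periods)] - 1)),
               noisePower = noisePower * g^2)
  list(wave = Waveform(out, fs, sprintf("synth:f0=%g,seed=%d", f0Hz, as.integer(seed))),
       truth = truth)
}

#' Simulate a two-class feature cohort with known structure
#'
#' Class-conditional Gaussian features: healthy subjects have mean 0 on every
#' feature, PD subjects have mean `effectSizes[j]` (in within-class sd units)
#' on the informative features and 0 elsewhere; unit variances. Informative
#' features may be equicorrelated with coefficient `correlation`. Labels can
#' be flipped with probability `labelNoise`.
#'
#' @param nPerClass subjects per class (>= 2).
#' @param nFeatures number of features (named `f01`, `f02`, ...).
#' @param informative integer indices of informative features.
#' @param effectSizes mean separations for the informative features (recycled).
#' @param correlation within-informative-block equicorrelation in \[0, 1).
#' @param labelNoise probability of flipping a subject's label.
#' @param seed integer RNG seed.
#' @return a [FeatureTable-class] with one row per subject.
#' @export
synthCohort <- function(nPerClass = 30, nFeatures = 33, informative = integer(0),
                        effectSizes = numeric(0), correlation = 0,
                        labelNoise = 0, seed = 1L) {
  if (nPerClass < 2) .err("phonoPD_spec_error", "need at least 2 subjects per class")
  if (length(informative) && (min(informative) < 1 || max(informative) > nFeatures))
    .err("phonoPD_spec_error", "informative indices out of range")
  if (correlation < 0 || correlation >= 1)
    .err("phonoPD_spec_error", "correlation must lie in [0, 1)")
  set.seed(as.integer(seed))
  n <- 2L * nPerClass
  eff <- numeric(nFeatures)
  if (length(informative))
    eff[informative] <- rep_len(effectSizes, length(informative))
  X <- matrix(stats::rnorm(n * nFeatures), n, nFeatures)
  if (correlation > 0 && length(informative) > 1) {
    shared <- stats::rnorm(n)
    X[, informative] <- sqrt(correlation) * shared +
      sqrt(1 - correlation) * X[, informative]
  }
  label <- rep(c("PD", "healthy"), each = nPerClass)
  X <- X + outer(as.numeric(label == "PD"), eff)
  if (labelNoise > 0) {
    flip <- stats::runif(n) < labelNoise
    label[flip] <- ifelse(label[flip] == "PD", "healthy", "PD")
  }
  fn <- sprintf("f%02d", seq_len(nFeatures))
  d <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                  recording_id = "r1",
                  label = label,
                  sex = rep_len(c("male", "female"), n),
                  age = sample(51:87, n, replace = TRUE),
                  stringsAsFactors = FALSE)
  d[fn] <- as.data.frame(X)
  new("FeatureTable", data = d, featureNames = fn)
}

#' Apply a per-feature affine covariate shift
#'
#' Produces the "second database" sibling of a simulated cohort by mapping
#' each listed feature `x` to `shiftScale * x + shiftMean`, emulating a
#' recording-condition change between cohorts.
#'
#' @param ft a [FeatureTable-class].
#' @param shiftMean,shiftScale affine shift parameters (recycled per feature).
#' @param features feature names to shift (default: all).
#' @return the shifted [FeatureTable-class].
#' @export
applyCovariateShift <- function(ft, shiftMean = 0, shiftScale = 1,
                                features = featureNames(ft)) {
  d <- tableData(ft)
  features <- setdiff(features, "sex")
  sm <- rep_len(shiftMean, length(features))
  ss <- rep_len(shiftScale, length(features))
  for (i in seq_along(features)) d[[features[i]]] <- ss[i] * d[[features[i]]] + sm[i]
  new("FeatureTable", data = d, featureNames = featureNames(ft))
}

#' Exact fractional Gaussian noise by circulant embedding
#'
#' Davies-Harte synthesis of fractional Gaussian noise with Hurst exponent
#' `H`: the target autocovariance is embedded in a circulant matrix whose
#' eigenvalues are obtained by FFT, giving a sample with exactly the fGn
#' spectrum. Used as an independent oracle for the DFA Hurst estimator.
#'
#' @param n sample length (power of two recommended).
#' @param H Hurst exponent in (0, 1).
#' @param seed integer RNG seed.
#' @return numeric vector of length `n`.
#' @export
fgnDaviesHarte <- function(n, H, seed = 1L) {
  set.seed(as.integer(seed))
  k <- 0:n
  gamma <- 0.5 * (abs(k - 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k + 1)^(2 * H))
  circ <- c(gamma[seq_len(n)], gamma[n + 1], rev(gamma[2:n]))
  lambda <- Re(stats::fft(circ))
  lambda[lambda < 0] <- 0  # clip tiny negative eigenvalues from rounding
  m <- 2 * n
  z <- complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
  w <- stats::fft(sqrt(lambda / (2 * m)) * z)
  Re(w[seq_len(n)]) * sqrt(2)
}

#' Binomial multiplicative cascade
#'
#' A dyadic multiplicative cascade: mass 1 on \[0, 1\] is repeatedly split
#' between half-intervals with weights `p` and `1 - p`, the weight order
#' randomized per split. The resulting measure has an analytic multifractal
#' spectrum with singularity strengths spanning
#' `[-log2(max(p, 1-p)), -log2(min(p, 1-p))]`; used as the oracle for the
#' multifractal spectrum width estimator.
#'
#' @param levels number of dyadic refinement levels (series length `2^levels`).
#' @param p weight in (0, 1), `p != 0.5` for a genuinely multifractal measure.
#' @param seed integer RNG seed controlling the per-split weight order.
#' @return numeric vector of cell masses, length `2^levels`.
#' @export
binomialCascade <- function(levels = 14, p = 0.6, seed = 1L) {
  set.seed(as.integer(seed))
  x <- 1
  for (l in seq_len(levels)) {
    swap <- stats::runif(length(x)) < 0.5
    left <- ifelse(swap, 1 - p, p)
    x <- as.vector(rbind(x * left, x * (1 - left)))
  }
  x
}
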