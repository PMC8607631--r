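# Cycle detection and the acoustic feature extractors, validated against the
# synthesizer's cycle-level ground truth and closed forms.

fakeCycles <- function(periodSamples, n = 40, fs = 44100L) {
  onsets <- cumsum(c(100, rep(periodSamples, n)))
  new("CycleSeries", onsets = onsets, periodsS = diff(onsets) / fs,
      peakAmps = rep(1, n), openS = numeric(0), closedS = numeric(0),
      rateHz = fs)
}

test_that("cycle detection recovers f0 and truth onsets on a clean vowel", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, seed = 3)
  cyc <- detectCycles(sv$wave)
  expect_equal(1 / mean(cyclePeriods(cyc)), 120, tolerance = 1 / 120)
  on <- cycleOnsets(cyc)
  tru <- cycleOnsets(sv$truth)
  # one mark per glottal cycle, at a constant intra-cycle phase offset
  expect_equal(length(on), length(tru))
  d <- on - tru
  expect_lt(max(abs(d - median(d))), 2)
})

test_that("a pure sinusoid yields the closed-form period", {
  x <- sin(2 * pi * 100 * (0:44099) / 44100)
  cyc <- detectCycles(Waveform(x))
  expect_equal(mean(cyclePeriods(cyc)) * 44100, 441, tolerance = 1 / 441)
})

test_that("white noise is rejected as unvoiced", {
  set.seed(41)
  expect_error(detectCycles(Waveform(rnorm(44100) * 0.1)),
               class = "phonoPD_unvoiced_error")
})

test_that("local jitter and shimmer match hand-evaluated formulas", {
  altP <- fakeCycles(441)  # replace periods with alternating 10.0/10.2 ms
  altP@periodsS <- rep(c(0.0100, 0.0102), 20)
  expect_equal(jitterLocal(altP), 100 * 0.0002 / 0.0101, tolerance = 1e-10)
  expect_equal(jitterLocal(fakeCycles(441)), 0)
  altA <- fakeCycles(441)
  altA@peakAmps <- rep(c(1.0, 0.9), 20)
  expect_equal(shimmerLocal(altA), 100 * 0.1 / 0.95, tolerance = 1e-10)
  expect_equal(shimmerLocal(fakeCycles(441)), 0)
  one <- fakeCycles(441, n = 1)
  expect_error(jitterLocal(one), class = "phonoPD_insufficient_cycles_error")
  expect_error(shimmerLocal(one), class = "phonoPD_insufficient_cycles_error")
})

test_that("extracted jitter and shimmer match the truth-cycle oracle", {
  svJ <- cachedVowel(f0Hz = 120, durationS = 1, jitterPct = 2, seed = 11)
  cyc <- detectCycles(svJ$wave)
  expect_rel(jitterLocal(cyc), jitterLocal(svJ$truth), relTol = 0.10)
  svS <- cachedVowel(f0Hz = 120, durationS = 1, shimmerPct = 3, seed = 12)
  cycS <- detectCycles(svS$wave)
  expect_rel(shimmerLocal(cycS), shimmerLocal(svS$truth), relTol = 0.10)
})

test_that("HNR hits the clip ceiling on clean vowels and is negative on noise", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, seed = 13)
  cyc <- detectCycles(sv$wave)
  expect_gte(hnrDb(sv$wave, cyc), 29)
  set.seed(42)
  nz <- Waveform(rnorm(44100) * 0.3)
  expect_lte(hnrDb(nz, fakeCycles(441)), 0)
})

test_that("HNR recovers synthesized noise levels within 3 dB", {
  for (h in c(20, 10)) {
    sv <- cachedVowel(f0Hz = 120, durationS = 1, hnrDb = h, seed = 13)
    cyc <- detectCycles(sv$wave)
    expect_lt(abs(hnrDb(sv$wave, cyc) - h), 3)
  }
})

test_that("CPP separates a vowel from equal-RMS noise and is deterministic", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, seed = 5)
  v <- samples(sv$wave)
  set.seed(43)
  nz <- rnorm(44100)
  nz <- nz * sqrt(mean(v^2) / mean(nz^2))
  cppV <- cppDb(sv$wave)
  expect_gte(cppV - cppDb(Waveform(nz)), 5)
  expect_identical(cppV, cppDb(sv$wave))
})

test_that("GNE is high for clean phonation, low for noise, ordered in between", {
  g <- vapply(c(Inf, 20, 10), function(h) {
    gne(cachedVowel(f0Hz = 120, durationS = 1, hnrDb = h, seed = 6)$wave)
  }, 0)
  expect_gte(g[1], 0.8)
  expect_true(all(diff(g) < 0))
  set.seed(44)
  gN <- gne(Waveform(rnorm(44100)))
  expect_lte(gN, 0.6)
  expect_lt(gN, g[1])
})

test_that("zero-crossing rate has its closed forms", {
  x <- sin(2 * pi * 100 * (0:44099) / 44100 + 0.1)
  expect_equal(zcr(Waveform(x)), 200)
  expect_equal(zcr(Waveform(rep(0.5, 1000))), 0)
  set.seed(45)
  expect_equal(zcr(Waveform(rnorm(44100))), 44100 / 2, tolerance = 0.02)
})

test_that("glottal quotients vanish for identical cycles and grow with jitter", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, seed = 7)
  cyc <- detectCycles(sv$wave)
  gq <- glottalQuotients(sv$wave, cyc)
  expect_lte(gq["gq_std_cycle_open"], 0.01)
  expect_lte(gq["gq_std_cycle_closed"], 0.01)
  expect_true(all(gq >= 0, na.rm = TRUE))
  prc <- vapply(c(0, 1, 2, 4), function(j) {
    s <- cachedVowel(f0Hz = 120, durationS = 1, jitterPct = j, seed = 8)
    glottalQuotients(s$wave, detectCycles(s$wave))["gq_prc5_95"]
  }, 0)
  expect_true(all(diff(prc) > 0))
})

test_that("MFCCs are gain invariant, deterministic, and separate vowels", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, seed = 7)
  m1 <- mfcc13(sv$wave)
  expect_length(m1, 13)
  m2 <- mfcc13(Waveform(2 * samples(sv$wave), 44100))
  expect_lt(max(abs(m1 - m2)), 1e-6)
  expect_identical(m1, mfcc13(sv$wave))
  svI <- cachedVowel(f0Hz = 120, durationS = 1, seed = 7,
                     formants = list(c(300, 80), c(2300, 120), c(3000, 160)))
  expect_gt(sqrt(sum((m1 - mfcc13(svI$wave))^2)), 1)
})

test_that("acoustic features are gain and polarity invariant", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, jitterPct = 1, shimmerPct = 2,
                    hnrDb = 20, seed = 9)
  w <- sv$wave
  cyc <- detectCycles(w)
  for (c2 in list(0.35, -1)) {
    w2 <- Waveform(c2 * samples(w), 44100)
    cyc2 <- detectCycles(w2)
    expect_equal(jitterLocal(cyc2), jitterLocal(cyc), tolerance = 1e-6)
    expect_equal(shimmerLocal(cyc2), shimmerLocal(cyc), tolerance = 1e-6)
    expect_equal(hnrDb(w2, cyc2), hnrDb(w, cyc), tolerance = 1e-6)
    expect_equal(cppDb(w2), cppDb(w), tolerance = 1e-6)
    if (c2 > 0) {
      expect_equal(zcr(w2), zcr(w), tolerance = 1e-6)
    } else {
      # zeros attach to the preceding sign, so polarity can move a crossing
      expect_lt(abs(zcr(w2) - zcr(w)), 2.5)
    }
    expect_equal(mfcc13(w2), mfcc13(w), tolerance = 1e-6)
  }
})

test_that("the full acoustic row is named and finite where defined", {
  sv <- cachedVowel(f0Hz = 180, durationS = 1, jitterPct = 1, shimmerPct = 3,
                    hnrDb = 15, seed = 10)
  f <- extractAcousticFeatures(sv$wave)
  expect_length(f, 22)
  expect_true(all(c("jitter_pct", "gne", "mfcc_13") %in% names(f)))
  expect_true(all(is.finite(f[c("jitter_pct", "shimmer_pct", "cpp_db",
                                "hnr_db", "gne", "zcr_per_s")])))
  expect_true(f[["gne"]] >= 0 && f[["gne"]] <= 1)
})
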