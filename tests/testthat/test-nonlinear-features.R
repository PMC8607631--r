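# Nonlinear-dynamics and information-theoretic measures against closed forms
# and exact-construction oracles.

test_that("RPDE is near zero for periodic signals and high for noise", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, seed = 5)
  ds <- samples(sv$wave)[seq(1, 44100, by = 2)]
  expect_lte(rpde(ds), 0.2)
  set.seed(51)
  nz <- runif(22050) - 0.5
  expect_gte(rpde(nz, epsFrac = 0.25), 0.8)  # dense-recurrence regime
  expect_lt(rpde(ds), rpde(nz))
  for (s in 1:5) {
    set.seed(s)
    v <- rpde(rnorm(3000))
    expect_true(is.na(v) || (v >= 0 && v <= 1))
  }
})

test_that("correlation dimension sees a limit cycle as one-dimensional", {
  x <- sin(2 * pi * 120 * (0:22049) / 22050)
  d2 <- correlationDimension(x)
  expect_lt(abs(d2 - 1), 0.2)
  expect_identical(d2, correlationDimension(x))
  set.seed(52)
  dn <- correlationDimension(rnorm(22050))
  expect_gte(dn, 2.5)   # iid noise fills the embedding space
  expect_gt(dn, 2 * d2)
  expect_true(is.na(correlationDimension(rep(1, 22050))))
})

test_that("pitch period entropy: flat tracks score low, jumpy tracks high", {
  expect_lte(ppe(rep(120, 100)), 0.1)
  set.seed(53)
  jumpy <- 120 * 2^(runif(300, -3, 3) / 12)
  expect_gte(ppe(jumpy), 0.6)
  expect_equal(ppe(jumpy), ppe(2 * jumpy), tolerance = 1e-9)
  expect_error(ppe(rep(120, 30)), class = "phonoPD_insufficient_data_error")
})

test_that("DFA recovers the Hurst exponent of white and fractional noise", {
  hW <- mean(vapply(1:20, function(s) { set.seed(s); hurstDfa(rnorm(4096)) }, 0))
  expect_lt(abs(hW - 0.5), 0.1)
  hF <- mean(vapply(1:20, function(s) hurstDfa(fgnDaviesHarte(4096, 0.8, seed = s)), 0))
  expect_lt(abs(hF - 0.8), 0.1)
  expect_gte(hurstDfa(seq_len(4096) + 0), 1)
  expect_error(hurstDfa(rnorm(100)), class = "phonoPD_insufficient_data_error")
})

test_that("LZ complexity: constant and random sequences hit their limits", {
  expect_equal(lz2(rep(1, 4096)), 2 * 12 / 4096, tolerance = 1e-12)
  set.seed(54)
  expect_gte(lz2(rnorm(4096)), 0.8)
  expect_error(lz2(rnorm(10)), class = "phonoPD_insufficient_data_error")
})

test_that("compiled LZ76 parser agrees with the quadratic reference parser", {
  set.seed(55)
  for (len in c(1, 2, 5, 9, 12, 40, 200)) {
    for (r in 1:5) {
      bits <- sample(0:1, len, replace = TRUE)
      expect_identical(.lz76_count(as.integer(bits)), lzRefCount(bits))
    }
  }
})

test_that("permutation entropy spans its closed-form extremes", {
  expect_equal(permutationEntropy(1:1000), 0)
  set.seed(56)
  expect_gte(permutationEntropy(rnorm(1e4)), 0.98)
  for (s in 1:5) {
    set.seed(s)
    v <- permutationEntropy(sample(c(0, 0, 1), 200, replace = TRUE))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("amplitude-histogram entropy spans [0, 1] with exact extremes", {
  centers <- (seq_len(64) - 0.5) / 64 * 2 - 1  # one sample per bin
  expect_equal(shannonEntropy(rep(centers, 10)), 1)
  expect_equal(shannonEntropy(rep(0.7, 100)), 0)
  expect_equal(shannonEntropy(numeric(100)), 0)
  set.seed(57)
  expect_gte(shannonEntropy(runif(1e5) * 2 - 1), 0.99)
})

test_that("first AMI minimum lands at a quarter period for sinusoids", {
  x <- sin(2 * pi * 100 * (0:44099) / 44100 + 0.1)
  expect_rel(amiFirstMin(x, rateHz = 44100), 2.5, relTol = 0.10)
  set.seed(58)
  nz <- rnorm(22050)
  expect_lte(as.numeric(amiFirstMin(nz, rateHz = 22050)), 0.25)  # a few samples
  expect_identical(amiFirstMin(x, rateHz = 44100), amiFirstMin(x, rateHz = 44100))
})

test_that("first ACF zero matches the quarter-period closed form", {
  x <- sin(2 * pi * 100 * (0:44099) / 44100)
  expect_lt(abs(acfFirstZero(x, rateHz = 44100) - 2.5), 1000 / 44100)
  z <- vapply(1:20, function(s) { set.seed(s); acfFirstZero(rnorm(44100), rateHz = 44100) }, 0)
  expect_lte(mean(z), 3 * 1000 / 44100)  # ACF of iid noise dies within a few samples
  expect_error(acfFirstZero(rep(1, 1000)), class = "phonoPD_insufficient_data_error")
})

test_that("multifractal spectrum width matches the binomial-cascade oracle", {
  w <- mean(vapply(1:5, function(s) mfsw(binomialCascade(14, 0.6, seed = s)), 0))
  expect_lt(abs(w - log2(0.6 / 0.4)), 0.15)
  set.seed(60)
  wn <- mfsw(rnorm(8192))
  expect_lte(wn, 0.3)
  expect_gte(wn, 0)
})

test_that("scale-free measures are invariant to positive gain", {
  sv <- cachedVowel(f0Hz = 120, durationS = 1, jitterPct = 1, hnrDb = 20, seed = 9)
  x <- samples(sv$wave)[seq(1, 44100, by = 2)]
  x2 <- 3.7 * x
  expect_equal(rpde(x2), rpde(x), tolerance = 1e-6)
  expect_equal(lz2(x2), lz2(x), tolerance = 1e-6)
  expect_equal(permutationEntropy(x2), permutationEntropy(x), tolerance = 1e-6)
  expect_equal(shannonEntropy(x2), shannonEntropy(x), tolerance = 1e-6)
  expect_equal(hurstDfa(x2), hurstDfa(x), tolerance = 1e-6)
  expect_equal(as.numeric(amiFirstMin(x2, 22050)), as.numeric(amiFirstMin(x, 22050)),
               tolerance = 1e-9)
  expect_equal(acfFirstZero(x2, 22050), acfFirstZero(x, 22050), tolerance = 1e-9)
})
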