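# Independent brute-force oracles and shared fixtures.

# Quadratic-time LZ76 exhaustive-history parser over a character/integer
# sequence: each word is the longest prefix reproducible from the extended
# history plus one symbol.
lzRefCount <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  if (n == 0) return(0L)
  cnt <- 0L
  i <- 1L
  while (i <= n) {
    l <- 0L
    while (i + l <= n &&
           grepl(substr(s, i, i + l), substr(s, 1, i + l - 1), fixed = TRUE)) {
      l <- l + 1L
    }
    cnt <- cnt + 1L
    i <- i + l + 1L
  }
  cnt
}

# O(n^2) Mann-Whitney concordance AUC with ties counted one half.
aucRef <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Sort-and-interpolate first quartile, rounded half up, floored at 1.
quartileRef <- function(counts) {
  s <- sort(counts)
  h <- (length(s) - 1) * 0.25
  lo <- floor(h)
  q <- s[lo + 1] + (h - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
  max(1L, as.integer(floor(q + 0.5)))
}

# Textbook equal-variance two-sample t statistic.
tRef <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# Session-cached synthetic vowels (synthesis is deterministic in all args).
.synthCache <- new.env(parent = emptyenv())
cachedVowel <- function(...) {
  key <- paste(deparse(list(...)), collapse = "")
  if (is.null(.synthCache[[key]])) .synthCache[[key]] <- synthVowel(...)
  .synthCache[[key]]
}

expect_rel <- function(actual, expected, relTol, absFloor = 0) {
  tol <- max(abs(expected) * relTol, absFloor)
  expect_lt(abs(actual - expected), tol + 1e-12)
}
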