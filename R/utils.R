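# Internal numeric helpers.

# Centered running mean with truncated edge windows. For even w the window
# extends floor((w-1)/2) frames left and the remainder right.
.rollMeanCentered <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  left <- (w - 1L) %/% 2L
  right <- w - 1L - left
  idx <- seq_len(n)
  lo <- pmax(1L, idx - left)
  hi <- pmin(n, idx + right)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Wrap angles (deg) to (-180, 180].
.wrapDeg <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# Deterministic per-unit sub-seeds from one root seed.
.subSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Population variance (denominator n).
.popVar <- function(x) mean((x - mean(x))^2)
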