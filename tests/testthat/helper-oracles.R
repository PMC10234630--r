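# Independent oracles and small fixture builders used across the suite.

# Weighted second-moment matrix built by an explicit loop over individuals
# (independent of the crossprod path in the implementation).
bruteWeightedCov <- function(B, w) {
  k <- ncol(B)
  M <- matrix(0, k, k)
  for (i in seq_len(nrow(B)))
    M <- M + w[i] * tcrossprod(B[i, ])
  M / sum(w)
}

# Top eigenvector by plain power iteration (independent of eigen()).
powerIterTop <- function(M, iter = 500) {
  v <- rep(1, ncol(M)) / sqrt(ncol(M))
  for (i in seq_len(iter)) {
    v <- drop(M %*% v)
    v <- v / sqrt(sum(v^2))
  }
  v
}

# Population variance by explicit summation.
bruteVariance <- function(x) {
  m <- sum(x) / length(x)
  s <- 0
  for (xi in x) s <- s + (xi - m)^2
  s / length(x)
}

# Small cohort container from an individuals x bins value matrix; nStages = 1
# so any bin count is allowed in fixtures.
toyRE <- function(valuesByIndividual, experiment = NULL, condition = NULL,
                  nStages = 1L) {
  n <- nrow(valuesByIndividual)
  if (is.null(experiment)) experiment <- rep("e1", n)
  if (is.null(condition)) condition <- rep("ctrl", n)
  RoamingExperiment(t(valuesByIndividual), experiment = experiment,
                    condition = condition, nStages = nStages)
}

# Cosine similarity of two vectors.
cosSim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
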