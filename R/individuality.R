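# Temporal individuality machinery: fractional ranks, bias transform,
# weighted-covariance PCA, shuffle-null PC significance, score-variance
# permutation tests, consistency index and extreme-individual extraction.

#' Rank individuals within each experiment and time bin
#'
#' Within each experiment and each time bin, individuals are ranked in
#' ascending order of roaming fraction (higher roaming, higher rank); ties
#' receive fractional ranks (mean of the tied positions, so values
#' (0.1, 0.3, 0.3, 0.9) rank as (1, 2.5, 2.5, 4)). The result is stored as
#' the \code{"rank"} assay.
#'
#' @param re a \linkS4class{RoamingExperiment}, typically at 50 bins
#'   (10 per stage). Individuals with missing bins are dropped with a
#'   message; an experiment with fewer than 2 individuals is an error.
#' @return the \linkS4class{RoamingExperiment} with a \code{"rank"} assay.
#' @examples
#' m <- matrix(c(0.1, 0.3, 0.3, 0.9), nrow = 1)
#' re <- RoamingExperiment(rbind(m)[rep(1, 5), ], experiment = rep("e", 4),
#'                         condition = rep("c", 4))
#' rankValues(rankIndividuals(re))[1, ]
#' @export
rankIndividuals <- function(re) {
  stopifnot(is(re, "RoamingExperiment"))
  r <- roamingFraction(re)
  bad <- colSums(is.na(r)) > 0L
  if (any(bad)) {
    message("excluding ", sum(bad), " individual(s) with missing bins: ",
            paste(utils::head(colnames(r)[bad], 5L), collapse = ", "),
            if (sum(bad) > 5L) " ..." else "")
    re <- re[, !bad]
    r <- roamingFraction(re)
  }
  expt <- experimentLabels(re)
  sizes <- table(expt)
  if (any(sizes < 2L))
    stop("experiment(s) with fewer than 2 individuals: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  rk <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  for (e in unique(expt)) {
    cols <- expt == e
    rk[, cols] <- t(apply(r[, cols, drop = FALSE], 1L,
                          rank, ties.method = "average"))
  }
  SummarizedExperiment::assay(re, "rank") <- rk
  re
}

#' Transform ranks into behavioral biases
#'
#' Applies \code{b = (2 / n) * (r - 1/2) - 1} with n the size of the
#' individual's experiment, mapping ranks to the open interval (-1, 1): the
#' top- and bottom-ranked individuals get \code{1 - 1/n} and \code{-1 + 1/n},
#' the experiment median maps to 0, and every per-bin, per-experiment mean
#' bias is exactly zero (including under fractional ties). Stored as the
#' \code{"bias"} assay.
#'
#' @param re a \linkS4class{RoamingExperiment} with a \code{"rank"} assay
#'   (ranks are computed first if absent).
#' @return the \linkS4class{RoamingExperiment} with a \code{"bias"} assay.
#' @export
biasTransform <- function(re) {
  stopifnot(is(re, "RoamingExperiment"))
  if (!"rank" %in% SummarizedExperiment::assayNames(re))
    re <- rankIndividuals(re)
  rk <- rankValues(re)
  expt <- experimentLabels(re)
  nOf <- as.numeric(table(expt)[expt])
  b <- sweep(rk, 2L, nOf, function(r, n) (2 / n) * (r - 0.5) - 1)
  SummarizedExperiment::assay(re, "bias") <- b
  re
}

#' Weighted-covariance PCA of the bias matrix
#'
#' Each individual is weighted inversely to the number of individuals in its
#' condition, so every condition contributes equally. The components are the
#' eigenvectors of the weighted second-moment matrix
#' \code{M = sum_i w_i b_i b_i' / sum_i w_i} (no mean subtraction by default:
#' per-bin biases are zero-mean by construction; a centering toggle exists
#' for sensitivity checks). Component signs are fixed so the
#' largest-magnitude entry of each component is positive; scores are the
#' projections \code{t_ik = b_i . w_k}.
#'
#' @param x a \linkS4class{RoamingExperiment} with a \code{"bias"} assay
#'   (computed if absent), or a numeric individuals x bins bias matrix.
#' @param conditions condition label per individual (taken from colData when
#'   \code{x} is a RoamingExperiment).
#' @param center subtract the weighted mean bias before the decomposition
#'   (default FALSE).
#' @return a \linkS4class{BiasPCA}.
#' @export
weightedPCA <- function(x, conditions = NULL, center = FALSE) {
  if (is(x, "RoamingExperiment")) {
    if (!"bias" %in% SummarizedExperiment::assayNames(x))
      x <- biasTransform(x)
    if (is.null(conditions)) conditions <- conditionLabels(x)
    b <- t(biasValues(x))
  } else {
    b <- as.matrix(x)
  }
  n <- nrow(b)
  if (n < 2L) stop("at least 2 individuals are required")
  if (is.null(conditions)) conditions <- rep("all", n)
  conditions <- as.character(conditions)
  stopifnot(length(conditions) == n)
  w <- 1 / as.numeric(table(conditions)[conditions])
  bc <- b
  if (center)
    bc <- sweep(b, 2L, colSums(b * w) / sum(w), "-")
  m <- crossprod(bc * w, bc) / sum(w)
  eg <- eigen(m, symmetric = TRUE)
  comp <- eg$vectors
  # sign convention: largest-magnitude entry of each component positive
  for (j in seq_len(ncol(comp))) {
    i <- which.max(abs(comp[, j]))
    if (comp[i, j] < 0) comp[, j] <- -comp[, j]
  }
  colnames(comp) <- paste0("PC", seq_len(ncol(comp)))
  rownames(comp) <- colnames(b)
  scores <- bc %*% comp
  dimnames(scores) <- list(rownames(b), colnames(comp))
  new("BiasPCA", components = comp, eigenvalues = pmax(eg$values, 0),
      scores = scores, weights = w, conditions = conditions,
      centered = center)
}

#' Shuffle ranks independently within each time bin
#'
#' Permutes each bin's ranks independently within each experiment, preserving
#' every per-bin, per-experiment rank multiset. This is the null model used
#' for component significance: any temporal structure linking bins within an
#' individual is destroyed while the marginals are kept.
#'
#' @param re a \linkS4class{RoamingExperiment} with a \code{"rank"} assay.
#' @param seed integer seed.
#' @param pool if TRUE, permute each bin across the pooled cohort instead of
#'   within experiments (default FALSE, which preserves the
#'   experiment-size-dependent bias marginals).
#' @return a \linkS4class{RoamingExperiment} with shuffled \code{"rank"} (and
#'   recomputed \code{"bias"}, if present before).
#' @export
shuffleRanks <- function(re, seed = 1L, pool = FALSE) {
  stopifnot(is(re, "RoamingExperiment"))
  if (!"rank" %in% SummarizedExperiment::assayNames(re))
    re <- rankIndividuals(re)
  set.seed(as.integer(seed))
  expt <- if (pool) rep("pooled", ncol(re)) else experimentLabels(re)
  rk <- .shuffleRankMatrix(rankValues(re), expt)
  SummarizedExperiment::assay(re, "rank") <- rk
  if ("bias" %in% SummarizedExperiment::assayNames(re)) {
    SummarizedExperiment::assays(re)[["bias"]] <- NULL
    re <- biasTransform(re)
  }
  re
}

# permute each row (bin) within experiment groups; uses the current RNG state
.shuffleRankMatrix <- function(rk, expt) {
  for (e in unique(expt)) {
    cols <- which(expt == e)
    for (k in seq_len(nrow(rk)))
      rk[k, cols] <- rk[k, cols][sample.int(length(cols))]
  }
  rk
}

#' Shuffle-null significance of individuality dimensions
#'
#' Compares the observed inter-individual variance captured by each PC with
#' variances from shuffled rank datasets (per-bin shuffling within
#' experiments). Two modes follow the two published comparisons: in
#' \code{own_space} each shuffled dataset gets its own weighted PCA and the
#' same-numbered eigenvalue is recorded; in \code{original_space} the shuffled
#' biases are projected onto the original components and the weighted score
#' variance along each is recorded. The per-PC exceedance is the fraction of
#' replicates at or above the observed value; a PC is flagged significant
#' when its exceedance is below \code{alpha}.
#'
#' @param re a \linkS4class{RoamingExperiment} (rank/bias assays computed as
#'   needed).
#' @param nReps shuffle replicates (default 500; must be >= 1).
#' @param alpha significance level (default 0.05).
#' @param mode \code{"both"}, \code{"own_space"} or \code{"original_space"}.
#' @param seed integer seed.
#' @param nPCs number of leading PCs to report (default all).
#' @return \code{S4Vectors::DataFrame} with one row per PC: observed weighted
#'   score variance, exceedance and significance flag per mode; the shuffle
#'   null distributions are in \code{metadata(result)$null}.
#' @export
pcSignificance <- function(re, nReps = 500L, alpha = 0.05,
                           mode = c("both", "own_space", "original_space"),
                           seed = 1L, nPCs = NULL) {
  mode <- match.arg(mode)
  nReps <- as.integer(nReps)
  if (nReps < 1L) stop("nReps must be at least 1")
  re <- biasTransform(re)
  model <- weightedPCA(re)
  k <- length(model@eigenvalues)
  if (is.null(nPCs)) nPCs <- k
  nPCs <- min(nPCs, k)
  obs <- model@eigenvalues[seq_len(nPCs)]

  expt <- experimentLabels(re)
  nOf <- as.numeric(table(expt)[expt])
  w <- model@weights
  rk <- rankValues(re)
  doOwn <- mode %in% c("both", "own_space")
  doOrig <- mode %in% c("both", "original_space")
  nullOwn <- if (doOwn) matrix(NA_real_, nReps, nPCs)
  nullOrig <- if (doOrig) matrix(NA_real_, nReps, nPCs)
  set.seed(as.integer(seed))
  for (r in seq_len(nReps)) {
    srk <- .shuffleRankMatrix(rk, expt)
    sb <- t(sweep(srk, 2L, nOf, function(x, n) (2 / n) * (x - 0.5) - 1))
    if (doOwn) {
      m <- crossprod(sb * w, sb) / sum(w)
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      nullOwn[r, ] <- ev[seq_len(nPCs)]
    }
    if (doOrig) {
      sc <- sb %*% model@components[, seq_len(nPCs), drop = FALSE]
      nullOrig[r, ] <- colSums(sc^2 * w) / sum(w)
    }
  }
  exceed <- function(null) vapply(seq_len(nPCs), function(j)
    mean(null[, j] >= obs[j]), numeric(1))
  res <- S4Vectors::DataFrame(pc = seq_len(nPCs), observedVariance = obs)
  if (doOwn) {
    res$exceedanceOwn <- exceed(nullOwn)
    res$significantOwn <- res$exceedanceOwn < alpha
  }
  if (doOrig) {
    res$exceedanceOriginal <- exceed(nullOrig)
    res$significantOriginal <- res$exceedanceOriginal < alpha
  }
  S4Vectors::metadata(res) <- list(nReps = nReps, alpha = alpha, seed = seed,
                                   null = list(own = nullOwn,
                                               original = nullOrig))
  res
}

#' Inter-individual variance of PC scores
#'
#' The population variance (denominator n) of the scores of a subpopulation
#' along one individuality dimension - the dispersal parameter compared
#' between conditions.
#'
#' @param model a \linkS4class{BiasPCA}, or a numeric score vector.
#' @param ids individual ids (rownames of the score matrix) or indices;
#'   NULL uses everyone.
#' @param dim dimension (PC index, default 1).
#' @return a single variance.
#' @export
scoreVariance <- function(model, ids = NULL, dim = 1L) {
  s <- if (is(model, "BiasPCA")) model@scores[, dim] else as.numeric(model)
  if (!is.null(ids)) {
    if (is.character(ids) && !all(ids %in% names(s)))
      stop("unknown individual id(s): ",
           paste(setdiff(ids, names(s)), collapse = ", "))
    s <- s[ids]
  }
  if (length(s) == 0L) stop("empty subpopulation")
  .popVar(s)
}

#' Permutation test for a difference in score variance
#'
#' Tests whether two disjoint groups differ in inter-individual score
#' variance along one dimension. Individuals are randomly reassigned to two
#' groups of the original sizes; the two-sided statistic is
#' \code{|var_A - var_B|} and \code{p = (1 + #(perm >= observed)) /
#' (1 + nPerm)}.
#'
#' @param x a \linkS4class{BiasPCA} or a named numeric vector of scores.
#' @param groupA,groupB disjoint id vectors (or index vectors), each >= 2.
#' @param dim dimension when \code{x} is a model (default 1).
#' @param nPerm permutations (default 1000).
#' @param seed integer seed.
#' @return list with \code{p.value}, \code{observed} (the statistic),
#'   \code{varA}, \code{varB}, \code{nPerm} and \code{seed}.
#' @export
variancePermutationTest <- function(x, groupA, groupB, dim = 1L,
                                    nPerm = 1000L, seed = 1L) {
  s <- if (is(x, "BiasPCA")) x@scores[, dim] else x
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  a <- s[groupA]
  b <- s[groupB]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 individuals")
  if (anyNA(a) || anyNA(b)) stop("unknown ids or missing scores")
  obs <- abs(.popVar(a) - .popVar(b))
  pool <- c(a, b)
  na <- length(a)
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(nPerm), function(i) {
    idx <- sample.int(length(pool), na)
    abs(.popVar(pool[idx]) - .popVar(pool[-idx]))
  }, numeric(1))
  list(p.value = (1 + sum(perm >= obs)) / (1 + nPerm),
       observed = obs, varA = .popVar(a), varB = .popVar(b),
       nPerm = nPerm, seed = seed)
}

#' @rdname variancePermutationTest
#' @param ... passed on to \code{variancePermutationTest}.
#' @details \code{bootstrapVarianceTest} is an alias kept because the
#'   procedure is referred to by both names in the field's figure legends and
#'   methods descriptions; the resampling is a label permutation.
#' @export
bootstrapVarianceTest <- function(...) variancePermutationTest(...)

#' Consistency index of each individual
#'
#' For each individual, the log2 ratio of the number of time bins in which
#' its roaming fraction is above the within-experiment per-bin median to the
#' number of bins in which it is below. Bins tied with the median are
#' excluded from both counts; a zero count on either side is replaced by 0.5
#' to keep the index finite. An individual tied with the median in every bin
#' gets index 0 with a warning.
#'
#' @param re a \linkS4class{RoamingExperiment} (typically at 50 bins).
#' @return named numeric vector, one index per individual.
#' @examples
#' # 40 bins above / 10 below gives log2(4) = 2
#' @export
consistencyIndex <- function(re) {
  stopifnot(is(re, "RoamingExperiment"))
  r <- roamingFraction(re)
  expt <- experimentLabels(re)
  idx <- rep(NA_real_, ncol(r))
  names(idx) <- colnames(r)
  for (e in unique(expt)) {
    cols <- which(expt == e)
    med <- apply(r[, cols, drop = FALSE], 1L, median)
    for (i in cols) {
      above <- sum(r[, i] > med)
      below <- sum(r[, i] < med)
      if (above == 0 && below == 0) {
        warning("individual ", colnames(r)[i],
                " ties the per-bin median in every bin; index set to 0")
        idx[i] <- 0
      } else {
        if (above == 0) above <- 0.5
        if (below == 0) below <- 0.5
        idx[i] <- log2(above / below)
      }
    }
  }
  idx
}

#' Extract extreme individuals along an individuality dimension
#'
#' @param x a \linkS4class{BiasPCA} or a named score vector.
#' @param dim dimension (default 1).
#' @param fraction fraction at each extreme, in (0, 0.5); \code{ceiling(
#'   fraction * n)} individuals per side (default 0.15, the top and bottom
#'   15 percent).
#' @return list with \code{top} and \code{bottom} id vectors (ties broken by
#'   stable individual order).
#' @export
extremeIndividuals <- function(x, dim = 1L, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must lie strictly between 0 and 0.5")
  s <- if (is(x, "BiasPCA")) x@scores[, dim] else x
  n <- length(s)
  m <- ceiling(fraction * n)
  ids <- names(s)
  if (is.null(ids)) ids <- seq_len(n)
  ordTop <- order(-s, seq_len(n))
  ordBot <- order(s, seq_len(n))
  list(top = ids[ordTop[seq_len(m)]], bottom = ids[ordBot[seq_len(m)]])
}

#' Correlation between the consistency index and PC scores
#'
#' Absolute Pearson correlation (the component sign is conventional, so only
#' the magnitude is meaningful).
#'
#' @param index consistency index per individual.
#' @param scores matching score vector (same individuals, same order).
#' @return |Pearson r|.
#' @export
consistencyPC1Correlation <- function(index, scores) {
  stopifnot(length(index) == length(scores))
  if (var(index) == 0 || var(scores) == 0)
    stop("zero-variance input")
  abs(cor(index, scores))
}
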