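# Stage-level population statistics: per-stage means, relative-to-control
# effects, rank-sum tests with FDR control, size-matched comparisons.

#' Per-individual, per-stage behavioral means
#'
#' Averages each individual's roaming fraction (or roaming speed) over the
#' bins of each stage, skipping missing bins. A stage with no defined bins is
#' flagged NA.
#'
#' @param re a \linkS4class{RoamingExperiment} at any per-stage binning.
#' @param assay assay to average (default \code{"roaming"}).
#' @return \code{S4Vectors::DataFrame}, one row per individual x stage:
#'   \code{individual}, \code{condition}, \code{stage}, \code{mean}.
#' @export
stageMeans <- function(re, assay = "roaming") {
  stopifnot(is(re, "RoamingExperiment"))
  v <- SummarizedExperiment::assay(re, assay)
  stage <- binStage(re)
  perStage <- lapply(levels(stage), function(s) {
    m <- colMeans(v[stage == s, , drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    S4Vectors::DataFrame(individual = colnames(v),
                         condition = conditionLabels(re),
                         stage = factor(s, levels = levels(stage)),
                         mean = unname(m))
  })
  do.call(rbind, perStage)
}

#' Condition-level summary of stage means
#'
#' @param sm output of \code{\link{stageMeans}}.
#' @return \code{S4Vectors::DataFrame} with \code{condition}, \code{stage},
#'   \code{mean}, \code{sem}, \code{n} (defined individuals only).
#' @export
summarizeStageMeans <- function(sm) {
  keys <- unique(S4Vectors::DataFrame(condition = sm$condition,
                                      stage = sm$stage))
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- sm$condition == keys$condition[i] & sm$stage == keys$stage[i]
    x <- sm$mean[sel]
    x <- x[!is.na(x)]
    n <- length(x)
    S4Vectors::DataFrame(condition = keys$condition[i],
                         stage = keys$stage[i],
                         mean = if (n) mean(x) else NA_real_,
                         sem = if (n > 1) stats::sd(x) / sqrt(n) else NA_real_,
                         n = n)
  })
  do.call(rbind, rows)
}

#' Per-stage effect relative to a control condition
#'
#' Ratio of the treated condition's mean to the control condition's mean in
#' each stage. Stages where the control mean is zero are flagged undefined
#' (NA ratio, \code{undefined = TRUE}).
#'
#' @param sm output of \code{\link{stageMeans}}.
#' @param treated,control condition labels present in \code{sm}.
#' @return \code{S4Vectors::DataFrame} with \code{stage}, \code{treatedMean},
#'   \code{controlMean}, \code{ratio}, \code{undefined}.
#' @export
relativeEffect <- function(sm, treated, control) {
  s <- summarizeStageMeans(sm)
  stages <- levels(sm$stage)
  rows <- lapply(stages, function(st) {
    tm <- s$mean[s$condition == treated & s$stage == st]
    cm <- s$mean[s$condition == control & s$stage == st]
    if (!length(tm) || !length(cm))
      stop("condition missing for stage ", st)
    und <- is.na(cm) || cm == 0
    S4Vectors::DataFrame(stage = factor(st, levels = stages),
                         treatedMean = tm, controlMean = cm,
                         ratio = if (und) NA_real_ else tm / cm,
                         undefined = und)
  })
  do.call(rbind, rows)
}

#' Rank-sum group comparison per unit with FDR control
#'
#' Two-sided Wilcoxon rank-sum test for each unit (row of the value matrix:
#' a time bin or a stage), Benjamini-Hochberg adjustment across units, and
#' \code{-log10} of the adjusted p-values. A unit whose pooled values are
#' constant gets p = 1.
#'
#' @param values numeric matrix, units x individuals (a vector is treated as
#'   one unit).
#' @param groupA,groupB disjoint column ids or indices, each >= 2.
#' @param fdr significance level on the adjusted p-values (default 0.05).
#' @return \code{S4Vectors::DataFrame} with \code{unit}, \code{nA},
#'   \code{nB}, \code{p}, \code{pAdj}, \code{negLog10PAdj},
#'   \code{significant}.
#' @export
compareGroups <- function(values, groupA, groupB, fdr = 0.05) {
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1L,
                     dimnames = list("unit", names(values)))
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  a <- values[, groupA, drop = FALSE]
  b <- values[, groupB, drop = FALSE]
  if (ncol(a) < 2L || ncol(b) < 2L)
    stop("each group needs at least 2 individuals")
  p <- vapply(seq_len(nrow(values)), function(i) {
    xa <- a[i, ][!is.na(a[i, ])]
    xb <- b[i, ][!is.na(b[i, ])]
    pooled <- c(xa, xb)
    if (length(xa) < 1L || length(xb) < 1L || length(unique(pooled)) < 2L)
      return(1)
    suppressWarnings(wilcox.test(xa, xb, alternative = "two.sided")$p.value)
  }, numeric(1))
  pAdj <- p.adjust(p, method = "BH")
  un <- rownames(values)
  if (is.null(un)) un <- as.character(seq_len(nrow(values)))
  S4Vectors::DataFrame(unit = un, nA = ncol(a), nB = ncol(b),
                       p = p, pAdj = pAdj,
                       negLog10PAdj = -log10(pAdj),
                       significant = pAdj < fdr)
}

#' Size-matched group comparison in running size windows
#'
#' Compares two groups within running windows over the pooled size range: 20
#' windows of width 10 percent of the range by default, centers evenly spaced
#' over \code{[min + w/2, max - w/2]}. Windows with fewer than 2 members per
#' group are flagged and excluded from the FDR adjustment.
#'
#' @param values numeric vector, one value per individual (e.g. a stage-mean
#'   roaming fraction).
#' @param sizes numeric vector of body sizes, same individuals.
#' @param groups factor/character with exactly two levels, same individuals.
#' @param nWindows number of running windows (default 20).
#' @param widthFrac window width as a fraction of the size range
#'   (default 0.10).
#' @param fdr significance level (default 0.05).
#' @return \code{S4Vectors::DataFrame} with one row per window: center and
#'   edges, per-group counts, p, BH-adjusted p, flags.
#' @export
sizeMatchedCompare <- function(values, sizes, groups, nWindows = 20L,
                               widthFrac = 0.10, fdr = 0.05) {
  stopifnot(length(values) == length(sizes),
            length(values) == length(groups))
  if (anyNA(sizes)) stop("sizes must be available for all individuals")
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups are required")
  rng <- range(sizes)
  if (diff(rng) == 0) stop("degenerate size range")
  w <- widthFrac * diff(rng)
  centers <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = nWindows)
  lv <- levels(groups)
  rows <- lapply(seq_len(nWindows), function(i) {
    inWin <- sizes >= centers[i] - w / 2 & sizes <= centers[i] + w / 2
    na <- sum(inWin & groups == lv[1])
    nb <- sum(inWin & groups == lv[2])
    p <- NA_real_
    if (na >= 2L && nb >= 2L) {
      xa <- values[inWin & groups == lv[1]]
      xb <- values[inWin & groups == lv[2]]
      pooled <- c(xa, xb)
      p <- if (length(unique(pooled[!is.na(pooled)])) < 2L) 1 else
        suppressWarnings(wilcox.test(xa, xb)$p.value)
    }
    S4Vectors::DataFrame(window = i, center = centers[i],
                         lo = centers[i] - w / 2, hi = centers[i] + w / 2,
                         nA = na, nB = nb, p = p, flagged = is.na(p))
  })
  res <- do.call(rbind, rows)
  res$pAdj <- NA_real_
  ok <- !res$flagged
  res$pAdj[ok] <- p.adjust(res$p[ok], method = "BH")
  res$significant <- !is.na(res$pAdj) & res$pAdj < fdr
  res
}
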