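# Ranking, bias transform, weighted PCA, shuffle nulls, permutation tests,
# consistency index.

test_that("fractional ranking reproduces the tie convention", {
  vals <- matrix(c(0.1, 0.3, 0.3, 0.9), nrow = 4, ncol = 5)  # 5 bins
  re <- rankIndividuals(toyRE(vals))
  expect_equal(unname(rankValues(re)[1, ]), c(1, 2.5, 2.5, 4))
  # strictly increasing values rank 1..n
  re2 <- rankIndividuals(toyRE(matrix(seq(0.1, 0.6, 0.1), 6, 3)))
  expect_equal(unname(rankValues(re2)[2, ]), 1:6)
  # all equal, n = 5: every rank is 3
  re3 <- rankIndividuals(toyRE(matrix(0.4, 5, 4)))
  expect_true(all(rankValues(re3) == 3))
  # an experiment with a single individual is rejected
  expect_error(rankIndividuals(toyRE(matrix(0.5, 3, 4),
                                     experiment = c("a", "a", "b"))),
               "fewer than 2")
})

test_that("ranking is within-experiment, not pooled", {
  vals <- rbind(c(0.9, 0.9), c(0.1, 0.1), c(0.8, 0.8), c(0.2, 0.2))
  re <- rankIndividuals(toyRE(vals, experiment = c("a", "a", "b", "b")))
  expect_equal(unname(rankValues(re)[1, ]), c(2, 1, 2, 1))
})

test_that("bias transform matches the closed form and its endpoints", {
  vals <- matrix(c(0.1, 0.3, 0.3, 0.9), nrow = 4, ncol = 5)
  re <- biasTransform(toyRE(vals))
  expect_equal(unname(biasValues(re)[1, ]), c(-0.75, 0, 0, 0.75))
  # endpoints +/- (1 - 1/n) and median 0 for odd n
  for (n in c(5, 8, 13)) {
    b <- biasValues(biasTransform(toyRE(matrix(runif(n * 5), n, 5))))
    expect_equal(max(b), 1 - 1 / n)
    expect_equal(min(b), -1 + 1 / n)
  }
  b5 <- biasValues(biasTransform(toyRE(matrix(c(1, 2, 3, 4, 5) / 10, 5, 2))))
  expect_equal(unname(b5[1, 3]), 0)  # median rank (n + 1) / 2 -> bias 0
})

test_that("per-bin, per-experiment mean bias is exactly zero under ties", {
  set.seed(31)
  for (rep in 1:5) {
    vals <- matrix(sample(seq(0, 1, 0.1), 12 * 6, replace = TRUE), 12, 6)
    re <- biasTransform(toyRE(vals,
                              experiment = rep(c("a", "b"), each = 6)))
    b <- biasValues(re)
    for (e in c("a", "b")) {
      cols <- experimentLabels(re) == e
      expect_equal(unname(rowSums(b[, cols])), rep(0, 6),
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted PCA with equal weights matches the brute-force oracle", {
  set.seed(17)
  B <- matrix(rnorm(6 * 4), 6, 4)
  m <- weightedPCA(B)
  # independent route: loop-built second-moment matrix + power iteration
  M <- bruteWeightedCov(B, rep(1 / 6, 6))
  top <- powerIterTop(M)
  expect_gt(cosSim(pcComponents(m)[, 1], top), 1 - 1e-10)
  eg <- eigen(M, symmetric = TRUE)
  expect_equal(m@eigenvalues, eg$values, tolerance = 1e-10)
  for (j in 1:4)
    expect_gt(cosSim(pcComponents(m)[, j], eg$vectors[, j]), 1 - 1e-10)
  # sign convention: largest-magnitude entry positive
  for (j in 1:4) {
    comp <- pcComponents(m)[, j]
    expect_gt(comp[which.max(abs(comp))], 0)
  }
})

test_that("PCA reconstruction identity holds on random inputs", {
  set.seed(18)
  for (rep in 1:3) {
    B <- matrix(rnorm(15 * 8), 15, 8)
    cond <- sample(c("a", "b"), 15, replace = TRUE)
    m <- weightedPCA(B, conditions = cond)
    expect_lt(max(abs(B - pcScores(m) %*% t(pcComponents(m)))), 1e-10)
    # Parseval: weighted score variance sums to total weighted bias variance
    w <- m@weights
    expect_equal(sum(colSums(pcScores(m)^2 * w) / sum(w)),
                 sum(colSums(B^2 * w) / sum(w)), tolerance = 1e-10)
    expect_equal(colSums(pcScores(m)^2 * w) / sum(w), unname(m@eigenvalues),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("antisymmetric pair yields a single perfect component", {
  b <- c(0.5, -0.25, 0.75, -0.5)
  m <- weightedPCA(rbind(b, -b))
  expect_gt(cosSim(pcComponents(m)[, 1], b), 1 - 1e-12)
  expect_equal(explainedVariance(m)[1], 1)
})

test_that("condition weighting recovers minority patterns unweighted PCA loses", {
  set.seed(19)
  k <- 20
  pat1 <- rep(c(1, -1), each = k / 2) / sqrt(k)
  pat2 <- rep(c(1, -1), k / 2) / sqrt(k)       # orthogonal to pat1
  nA <- 1000; nB <- 10
  # minority signal sized below the unweighted detection edge but far above
  # it once conditions are equally weighted
  mkGroup <- function(n, pat, sdc) t(vapply(seq_len(n), function(i)
    rnorm(1, 0, sdc) * pat + rnorm(k, 0, 0.3), numeric(k)))
  B <- rbind(mkGroup(nA, pat1, 1), mkGroup(nB, pat2, 1.5))
  cond <- rep(c("big", "small"), c(nA, nB))
  mW <- weightedPCA(B, conditions = cond)
  c1 <- max(cosSim(pcComponents(mW)[, 1], pat1),
            cosSim(pcComponents(mW)[, 2], pat1))
  c2 <- max(cosSim(pcComponents(mW)[, 1], pat2),
            cosSim(pcComponents(mW)[, 2], pat2))
  expect_gt(c1, 0.9)
  expect_gt(c2, 0.9)
  # unweighted PCA buries the minority condition's pattern
  mU <- weightedPCA(B)
  expect_lt(max(cosSim(pcComponents(mU)[, 1], pat2),
                cosSim(pcComponents(mU)[, 2], pat2)), 0.9)
  # equal condition sizes: weighted equals unweighted component-wise
  Beq <- rbind(mkGroup(50, pat1, 1), mkGroup(50, pat2, 1))
  mE <- weightedPCA(Beq, conditions = rep(c("a", "b"), each = 50))
  mN <- weightedPCA(Beq)
  for (j in 1:4)
    expect_gt(cosSim(pcComponents(mE)[, j], pcComponents(mN)[, j]),
              1 - 1e-10)
})

test_that("per-bin shuffling preserves rank multisets and is reproducible", {
  spec <- populationSpec(24, nExperiments = 2, seed = 8)
  st <- individualityStructure("homogeneous", strengths = 1)
  re <- rankIndividuals(generateRoamingMatrix(spec, st))
  sh1 <- shuffleRanks(re, seed = 5)
  sh2 <- shuffleRanks(re, seed = 5)
  sh3 <- shuffleRanks(re, seed = 6)
  expect_identical(rankValues(sh1), rankValues(sh2))
  expect_false(identical(rankValues(sh1), rankValues(sh3)))
  rk <- rankValues(re)
  rs <- rankValues(sh1)
  for (e in unique(experimentLabels(re))) {
    cols <- experimentLabels(re) == e
    for (k in c(1, 25, 50))
      expect_identical(unname(sort(rs[k, cols])),
                       unname(sort(rk[k, cols])))
  }
})

test_that("shuffling collapses planted structure toward the flat spectrum", {
  spec <- populationSpec(200, seed = 12)
  st <- individualityStructure("homogeneous", strengths = 2)
  re <- biasTransform(generateRoamingMatrix(spec, st))
  evReal <- explainedVariance(weightedPCA(re))[1]
  evShuf <- explainedVariance(weightedPCA(shuffleRanks(re, seed = 2)))[1]
  expect_gt(evReal, 0.3)
  expect_lt(evShuf, 0.1)   # toward 1/50 of the total
})

test_that("planted structure gives PC1 exceedance 0 in both shuffle modes", {
  spec <- populationSpec(120, seed = 13)
  st <- individualityStructure("homogeneous", strengths = 2)
  re <- generateRoamingMatrix(spec, st)
  sig <- pcSignificance(re, nReps = 100, seed = 4, nPCs = 3)
  expect_identical(sig$exceedanceOwn[1], 0)
  expect_identical(sig$exceedanceOriginal[1], 0)
  expect_true(sig$significantOwn[1] && sig$significantOriginal[1])
  expect_error(pcSignificance(re, nReps = 0), "nReps")
})

test_that("score variance matches brute force and the empty set errors", {
  set.seed(23)
  B <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(paste0("w", 1:5), NULL))
  m <- weightedPCA(B)
  expect_equal(scoreVariance(m, dim = 2), bruteVariance(pcScores(m)[, 2]))
  expect_equal(scoreVariance(m, ids = c("w1", "w3", "w4")),
               bruteVariance(pcScores(m)[c(1, 3, 4), 1]))
  expect_error(scoreVariance(m, ids = character(0)), "empty")
  expect_identical(scoreVariance(rep(2, 10)), 0)
})

test_that("variance permutation test is valid and detects real differences", {
  set.seed(41)
  # same-distribution groups: p bounded below by 1/(nPerm + 1), not tiny
  a <- rnorm(40); b <- rnorm(40)
  s <- c(a, b); names(s) <- paste0("i", seq_along(s))
  p0 <- variancePermutationTest(s, paste0("i", 1:40), paste0("i", 41:80),
                                nPerm = 200, seed = 2)
  expect_gte(p0$p.value, 1 / 201)
  # group B a permutation of group A's values: observed statistic 0, p ~ 1
  sPerm <- c(a, sample(a)); names(sPerm) <- paste0("i", seq_along(sPerm))
  pEq <- variancePermutationTest(sPerm, paste0("i", 1:40),
                                 paste0("i", 41:80), nPerm = 200, seed = 3)
  expect_gt(pEq$p.value, 0.95)
  # variances 1 vs 9 with n = 50: detected
  s2 <- c(rnorm(50, 0, 1), rnorm(50, 0, 3))
  names(s2) <- paste0("i", seq_along(s2))
  p1 <- variancePermutationTest(s2, paste0("i", 1:50), paste0("i", 51:100),
                                nPerm = 500, seed = 4)
  expect_lt(p1$p.value, 0.05)
  expect_error(variancePermutationTest(s2, paste0("i", 1:10),
                                       paste0("i", 10:20)), "disjoint")
  # alias
  expect_identical(bootstrapVarianceTest(s2, paste0("i", 1:50),
                                         paste0("i", 51:100),
                                         nPerm = 100, seed = 9)$p.value,
                   variancePermutationTest(s2, paste0("i", 1:50),
                                           paste0("i", 51:100),
                                           nPerm = 100, seed = 9)$p.value)
})

test_that("permutation p-values are near-uniform under the null", {
  set.seed(57)
  ps <- replicate(60, {
    s <- rnorm(40)
    names(s) <- paste0("i", 1:40)
    variancePermutationTest(s, paste0("i", 1:20), paste0("i", 21:40),
                            nPerm = 99, seed = sample.int(1e6, 1))$p.value
  })
  # coarse uniformity: mean near 0.5 and no excess below 0.05
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_lte(sum(ps <= 0.05), 9)  # binomial(60, 0.05) upper tail
})

test_that("consistency index reproduces hand-computed cases", {
  # individual above the median in 40 bins and below in 10: log2(4) = 2
  set.seed(61)
  n <- 9
  base <- matrix(runif(n * 50, 0.4, 0.6), n, 50)
  target <- ifelse(seq_len(50) <= 40, 0.95, 0.05)
  vals <- rbind(base, target)
  ci <- consistencyIndex(toyRE(vals))
  expect_equal(unname(ci[n + 1]), 2)
  # balanced individual: 25 above, 25 below -> 0
  target2 <- rep(c(0.95, 0.05), 25)
  ci2 <- consistencyIndex(toyRE(rbind(base, target2)))
  expect_equal(unname(ci2[n + 1]), 0)
  # always above: zero count replaced by 0.5 -> log2(50 / 0.5)
  ci3 <- consistencyIndex(toyRE(rbind(base, rep(0.95, 50))))
  expect_equal(unname(ci3[n + 1]), log2(100))
})

test_that("reflecting values about the per-bin median negates the index", {
  set.seed(62)
  vals <- matrix(runif(8 * 50, 0.4, 0.6), 8, 50)
  med <- apply(vals, 2, median)
  reflected <- sweep(-vals, 2, 2 * med, "+")
  ci <- consistencyIndex(toyRE(vals))
  ciR <- consistencyIndex(toyRE(reflected))
  expect_equal(unname(ciR), unname(-ci), tolerance = 1e-12)
})

test_that("extreme individuals use ceiling counts and stable ordering", {
  s <- seq(20, 1)
  names(s) <- paste0("w", 1:20)
  ex <- extremeIndividuals(s, fraction = 0.15)
  expect_identical(ex$top, paste0("w", 1:3))
  expect_identical(ex$bottom, paste0("w", 20:18))
  expect_error(extremeIndividuals(s, fraction = 0.5), "fraction")
  # ties broken by stable individual order
  st <- c(a = 1, b = 1, c = 1, d = 0)
  expect_identical(extremeIndividuals(st, fraction = 0.3)$top, c("a", "b"))
})

test_that("consistency/PC correlation behaves at the extremes", {
  x <- rnorm(30)
  expect_equal(consistencyPC1Correlation(x, x), 1)
  expect_equal(consistencyPC1Correlation(x, -x), 1)
  expect_error(consistencyPC1Correlation(rep(1, 30), x), "zero-variance")
})
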