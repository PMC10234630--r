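# Trajectory processing: kinematics, stage detection, classification,
# age normalization.

straightTraj <- function(n = 120, step = 50, fps = 3) {
  WormTrajectory(time = (seq_len(n) - 1) / fps,
                 x = (seq_len(n) - 1) * step, y = rep(0, n), fps = fps)
}

test_that("rolling kinematics on canonical paths", {
  # straight line, 50 um per frame at 3 fps
  kin <- rollingKinematics(straightTraj())
  expect_equal(unname(speed(kin)), rep(150, 120), tolerance = 1e-9)
  expect_equal(unname(angularVelocity(kin)), rep(0, 120), tolerance = 1e-9)

  # stationary worm: speed 0 and, with no heading, angular velocity 0
  still <- WormTrajectory(time = (0:99) / 3, x = rep(1, 100),
                          y = rep(2, 100))
  kin2 <- rollingKinematics(still)
  expect_true(all(speed(kin2) == 0))
  expect_true(all(angularVelocity(kin2) == 0))

  # square-wave path turning 90 degrees every frame: 90 * 3 = 270 deg/s
  n <- 120
  dirs <- matrix(c(1, 0, 0, 1), 2)[, rep(c(1, 2), length.out = n - 1)]
  sq <- WormTrajectory(time = (seq_len(n) - 1) / 3,
                       x = cumsum(c(0, dirs[1, ] * 50)),
                       y = cumsum(c(0, dirs[2, ] * 50)))
  kin3 <- rollingKinematics(sq)
  expect_equal(mean(angularVelocity(kin3)[!kin3@truncated]), 270,
               tolerance = 1e-9)
})

test_that("non-uniform sampling raises an error naming offending frames", {
  t <- (0:59) / 3
  t[31] <- t[31] + 0.2
  tr <- WormTrajectory(time = t, x = seq_len(60), y = rep(0, 60))
  expect_error(rollingKinematics(tr), "non-uniform sampling.*31")
})

test_that("edge frames with truncated windows are flagged", {
  kin <- rollingKinematics(straightTraj(100))
  w <- round(10 * 3)
  expect_true(all(kin@truncated[c(1, 100)]))
  expect_false(any(kin@truncated[(w + 1):(100 - w)]))
})

test_that("stage detection recovers constructed quiescent gaps", {
  p <- kinematicParams(stageDurationsH = rep(0.5, 5), lethargusH = 0.5)
  g <- generateTrajectory(p, seed = 11)
  kin <- rollingKinematics(g$trajectory)
  seg <- detectStages(kin)
  expect_lt(max(abs(stageBoundaries(seg) -
                    stageBoundaries(g$segmentation))), 150)
  # continuous activity: no qualifying gaps
  kinFlat <- rollingKinematics(straightTraj(20000))
  expect_error(detectStages(kinFlat), "segmentation error")
})

test_that("short spurious quiescent gaps are filtered by duration", {
  # 4 real gaps (30 min) plus one spurious 6-min gap
  fps <- 3
  segLen <- round(0.4 * 3600 * fps)
  gapLen <- round(0.5 * 3600 * fps)
  shortGap <- round(0.1 * 3600 * fps)
  sp <- rep(100, segLen)
  gapAt <- integer(0)
  for (i in 1:4) {
    gapAt <- c(gapAt, length(sp) + 1L)
    sp <- c(sp, rep(0, gapLen), rep(100, segLen))
  }
  sp <- c(sp, rep(0, shortGap), rep(100, segLen))  # spurious short gap
  n <- length(sp)
  tr <- WormTrajectory(time = (seq_len(n) - 1) / fps, x = cumsum(sp / fps),
                       y = rep(0, n))
  seg <- detectStages(rollingKinematics(tr))
  expect_identical(length(stageBoundaries(seg)), 4L)
  expect_equal(stageBoundaries(seg), gapAt + gapLen / 2, tolerance = 200)
})

test_that("diagonal classification follows the per-stage slopes", {
  # one frame per case via constant synthetic kinematics
  mk <- function(speed, ang, nFrames = 5) {
    new("KinematicSeries", speed = rep(speed, nFrames),
        angularVelocity = rep(ang, nFrames), windowSec = 10, fps = 3,
        truncated = rep(FALSE, nFrames))
  }
  segAdult <- StageSegmentation(c(2, 3, 4, 5), nFrames = 10)
  # frames 6.. are Adult (slope 1.5): 200/7.59 = 26.4 > 1.5 * 10/3.6 = 4.17
  st <- classifyStates(mk(200, 10, 10), segAdult)
  expect_identical(as.character(st[8]), "roaming")
  # L1 (slope 5): 26.4 > 5 * 2.78 = 13.9 -> roaming
  segL1 <- StageSegmentation(c(6, 7, 8, 9), nFrames = 10)
  st1 <- classifyStates(mk(200, 10, 10), segL1)
  expect_identical(as.character(st1[3]), "roaming")
  # L1 at angular velocity 20 deg/s: 26.4 <= 5 * 5.56 = 27.8 -> dwelling
  st2 <- classifyStates(mk(200, 20, 10), segL1)
  expect_identical(as.character(st2[3]), "dwelling")
  # speed 0 / angular velocity 0 is on the diagonal -> dwelling
  st3 <- classifyStates(mk(0, 0, 10), segL1)
  expect_identical(as.character(st3[3]), "dwelling")
  # zeroth speed bin -> dwelling even when straight
  st4 <- classifyStates(mk(5, 0, 10), segL1)
  expect_identical(as.character(st4[3]), "dwelling")
})

test_that("classification is scale-consistent and monotone in the slope", {
  set.seed(21)
  n <- 400
  kin <- new("KinematicSeries", speed = runif(n, 0, 250),
             angularVelocity = runif(n, 0, 150), windowSec = 10, fps = 3,
             truncated = rep(FALSE, n))
  seg <- StageSegmentation(c(80, 160, 240, 320), nFrames = n)
  base <- classifyStates(kin, seg)
  # multiply both bin widths and both kinematic channels by c
  cc <- 3.7
  kinScaled <- new("KinematicSeries", speed = kin@speed * cc,
                   angularVelocity = kin@angularVelocity * cc,
                   windowSec = 10, fps = 3, truncated = kin@truncated)
  cfgScaled <- classifierConfig(speedBinWidth = 7.59 * cc,
                                angularBinWidth = 3.6 * cc)
  expect_identical(classifyStates(kinScaled, seg, cfgScaled), base)
  # raising every slope can only shrink the roaming set
  for (mult in c(1.5, 3)) {
    stricter <- classifierConfig(slopes = c(L1 = 5, L2 = 2.5, L3 = 2.3,
                                            L4 = 2, Adult = 1.5) * mult)
    harder <- classifyStates(kin, seg, stricter)
    expect_true(all(which(harder == "roaming") %in%
                    which(base == "roaming")))
  }
})

test_that("age normalization yields exact bin counts and known patterns", {
  n <- 5 * 750
  seg <- StageSegmentation(c(750, 1500, 2250, 3000), nFrames = n)
  kin <- new("KinematicSeries", speed = rep(100, n),
             angularVelocity = rep(0, n), windowSec = 10, fps = 3,
             truncated = rep(FALSE, n))
  allRoam <- factor(rep("roaming", n),
                    levels = c("dwelling", "roaming", "quiescent"))
  b <- ageNormalize(allRoam, kin, seg, binsPerStage = 75)
  expect_identical(nrow(b), 375L)
  expect_true(all(b$roamingFraction == 1))
  expect_identical(nrow(ageNormalize(allRoam, kin, seg, 10)), 50L)

  # one stage with first half roaming, second half dwelling
  lab <- rep("dwelling", n)
  lab[1:375] <- "roaming"
  st <- factor(lab, levels = c("dwelling", "roaming", "quiescent"))
  b2 <- ageNormalize(st, kin, seg, binsPerStage = 75)
  l1 <- b2$roamingFraction[b2$stage == "L1"]
  expect_true(all(l1[1:37] == 1))
  expect_true(all(l1[39:75] == 0))
  expect_true(l1[38] > 0 && l1[38] < 1)
  # bins where every frame is quiescent are flagged missing
  qu <- factor(rep("quiescent", n),
               levels = c("dwelling", "roaming", "quiescent"))
  expect_true(all(is.na(ageNormalize(qu, kin, seg, 10)$roamingFraction)))
})

test_that("classify + bin recovers the generating per-stage fractions", {
  p <- kinematicParams(stageDurationsH = rep(0.5, 5), lethargusH = 0.5)
  for (sd in c(7, 42)) {
    g <- generateTrajectory(p, seed = sd)
    pr <- processTrajectory(g$trajectory, binsPerStage = 10)
    perStage <- tapply(pr$binned$roamingFraction, pr$binned$stage, mean,
                       na.rm = TRUE)
    expect_lt(max(abs(perStage - g$perStageRoaming)), 0.1)
  }
  # all-zero speeds classify as 100% dwelling
  still <- WormTrajectory(time = (0:3749) / 3, x = rep(0, 3750),
                          y = rep(0, 3750))
  seg <- StageSegmentation(c(750, 1500, 2250, 3000), nFrames = 3750)
  kin <- rollingKinematics(still)
  st <- classifyStates(kin, seg)
  expect_true(all(st[st != "quiescent"] == "dwelling"))
  expect_false(any(st == "roaming"))
})
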