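# Trajectory processing: rolling kinematics, lethargus/stage detection,
# roaming/dwelling classification, age-normalized binning.

#' Rolling speed and angular velocity of a trajectory
#'
#' Per-frame speed is the displacement from the previous frame times the frame
#' rate; heading is the direction of the displacement vector and angular
#' velocity the absolute wrapped heading change times the frame rate. Both are
#' then averaged over a centered rolling window of \code{round(windowSec *
#' fps)} frames. Stationary frames carry no heading; their angular velocity is
#' defined as 0. Edge frames with truncated windows are flagged.
#'
#' @param traj a \linkS4class{WormTrajectory} with uniform sampling; gaps
#'   raise an error listing the offending frames.
#' @param windowSec rolling window in seconds (default 10).
#' @return a \linkS4class{KinematicSeries} of the same length.
#' @examples
#' tr <- WormTrajectory(time = (0:99) / 3, x = (0:99) * 50 / 3, y = rep(0, 100))
#' kin <- rollingKinematics(tr)
#' range(speed(kin))  # 150 um/s throughout
#' @export
rollingKinematics <- function(traj, windowSec = 10) {
  stopifnot(is(traj, "WormTrajectory"))
  n <- length(traj@time)
  fps <- traj@fps
  w <- max(1L, round(windowSec * fps))
  if (n < w)
    stop("trajectory shorter (", n, " frames) than the rolling window (",
         w, " frames)")
  dt <- diff(traj@time)
  bad <- which(abs(dt - 1 / fps) > 0.25 / fps)
  if (length(bad))
    stop("non-uniform sampling at frame(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "")
  dx <- diff(traj@x)
  dy <- diff(traj@y)
  stepLen <- sqrt(dx^2 + dy^2)
  instSpeed <- c(stepLen[1L], stepLen) * fps

  # headings of displacement vectors; zero-length steps keep the last heading
  hd <- atan2(dy, dx) * 180 / pi
  hd[stepLen == 0] <- NA
  hdFill <- hd
  lastSeen <- NA_real_
  for (i in seq_along(hdFill)) {
    if (is.na(hdFill[i])) hdFill[i] <- lastSeen else lastSeen <- hdFill[i]
  }
  dh <- .wrapDeg(diff(hdFill))
  dh[is.na(dh)] <- 0                      # no heading yet -> no turning
  dh[stepLen[-1L] == 0] <- 0              # stationary frame -> no turning
  # dh[j] is the turn at frame j + 1; replicate at both edges
  instAng <- if (length(dh)) abs(c(dh[1L], dh, dh[length(dh)])) * fps
             else rep(0, n)

  ks <- new("KinematicSeries",
            speed = .rollMeanCentered(instSpeed, w),
            angularVelocity = .rollMeanCentered(instAng, w),
            windowSec = windowSec, fps = fps,
            truncated = seq_len(n) <= (w - 1L) %/% 2L |
                        seq_len(n) > n - (w - (w - 1L) %/% 2L - 1L))
  ks
}

#' Detect lethargus periods and segment a recording into stages
#'
#' The rolling speed is further smoothed (300-frame running mean); quiescent
#' spans are runs where the smoothed speed is at or below the given quantile
#' of the individual's own smoothed-speed distribution, lasting at least
#' \code{minQuiescenceMin} minutes. The four longest such spans are taken as
#' the lethargus periods and their midpoint frames become the stage
#' boundaries.
#'
#' @param kin a \linkS4class{KinematicSeries} spanning the full recording.
#' @param quiescenceQuantile quantile of the smoothed-speed distribution used
#'   as the quiescence threshold (default 0.05).
#' @param minQuiescenceMin minimum quiescent-span duration, minutes
#'   (default 20).
#' @param smoothFrames running-mean window for the additional smoothing
#'   (default 300 frames).
#' @return a \linkS4class{StageSegmentation}.
#' @export
detectStages <- function(kin, quiescenceQuantile = 0.05,
                         minQuiescenceMin = 20, smoothFrames = 300L) {
  stopifnot(is(kin, "KinematicSeries"))
  n <- length(kin@speed)
  smoothed <- .rollMeanCentered(kin@speed, as.integer(smoothFrames))
  thr <- quantile(smoothed, quiescenceQuantile, names = FALSE)
  # tolerance absorbs running-mean round-off when quiescent spans have
  # (near-)constant speed equal to the quantile value
  below <- smoothed <= thr + 1e-6
  minFrames <- minQuiescenceMin * 60 * kin@fps
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minFrames
  if (sum(keep) < 4L)
    stop("segmentation error: only ", sum(keep),
         " quiescent span(s) of >= ", minQuiescenceMin,
         " min found; 4 lethargus periods are required")
  spans <- cbind(start = starts[keep], end = ends[keep])
  lens <- spans[, "end"] - spans[, "start"] + 1L
  spans <- spans[order(-lens)[1:4], , drop = FALSE]
  spans <- spans[order(spans[, "start"]), , drop = FALSE]
  boundaries <- as.integer(floor((spans[, "start"] + spans[, "end"]) / 2))
  StageSegmentation(boundaries, nFrames = n, lethargusSpans = spans)
}

#' Classify frames as roaming, dwelling or quiescent
#'
#' Applies the per-stage diagonal in histogram-bin units: a frame in stage s
#' is roaming when \code{speed / speedBinWidth > slope_s * angularVelocity /
#' angularBinWidth}. On-diagonal frames and frames in the zeroth speed bin
#' (speed below one bin width) are dwelling. Frames inside the segmentation's
#' lethargus spans are labeled quiescent.
#'
#' @param kin a \linkS4class{KinematicSeries}.
#' @param seg a \linkS4class{StageSegmentation} covering the same frames.
#' @param cfg a \linkS4class{ClassifierConfig}.
#' @return factor per frame with levels dwelling, roaming, quiescent.
#' @export
classifyStates <- function(kin, seg, cfg = classifierConfig()) {
  stopifnot(is(kin, "KinematicSeries"), is(seg, "StageSegmentation"))
  n <- length(kin@speed)
  if (seg@nFrames != n)
    stop("kinematics (", n, " frames) and segmentation (", seg@nFrames,
         " frames) cover different spans")
  stage <- stageOfFrame(seg)
  sl <- cfg@slopes[as.character(stage)]
  if (anyNA(sl[!is.na(stage)]))
    stop("config error: missing slope for stage(s) ",
         paste(setdiff(levels(stage), names(cfg@slopes)), collapse = ", "))
  su <- kin@speed / cfg@speedBinWidth
  au <- kin@angularVelocity / cfg@angularBinWidth
  roam <- su > sl * au & floor(su) >= 1
  roam[is.na(roam)] <- FALSE
  lab <- ifelse(roam, "roaming", "dwelling")
  sp <- seg@lethargusSpans
  for (i in seq_len(nrow(sp)))
    if (sp[i, "end"] >= sp[i, "start"])
      lab[sp[i, "start"]:sp[i, "end"]] <- "quiescent"
  factor(lab, levels = c("dwelling", "roaming", "quiescent"))
}

#' Age-normalize classified behavior into per-stage time bins
#'
#' Divides each stage's frame span into \code{binsPerStage} equal-duration
#' windows and computes, per bin, the roaming fraction (roaming frames over
#' roaming + dwelling frames; quiescent frames are excluded from both) and the
#' mean rolling speed over roaming frames. Bins with no roaming/dwelling
#' frames get an NA fraction; bins with no roaming frames get an NA speed.
#'
#' @param states per-frame labels from \code{\link{classifyStates}}.
#' @param kin the matching \linkS4class{KinematicSeries}.
#' @param seg the \linkS4class{StageSegmentation}.
#' @param binsPerStage bins per stage: 75 (fine) or 10 (rank) typical.
#' @return \code{S4Vectors::DataFrame} with one row per bin: \code{bin},
#'   \code{stage}, \code{binInStage}, \code{roamingFraction},
#'   \code{roamingSpeed}, \code{nFrames}.
#' @export
ageNormalize <- function(states, kin, seg, binsPerStage = 75L) {
  stopifnot(is(seg, "StageSegmentation"),
            length(states) == seg@nFrames)
  binsPerStage <- as.integer(binsPerStage)
  starts <- c(seg@hatchFrame, seg@boundaries + 1L)
  ends <- c(seg@boundaries, seg@nFrames)
  out <- vector("list", 5L)
  for (s in seq_len(5L)) {
    frames <- starts[s]:ends[s]
    len <- length(frames)
    # equal-duration windows over the stage span
    binIdx <- pmin(binsPerStage,
                   floor((frames - starts[s]) / len * binsPerStage) + 1L)
    fr <- sp <- rep(NA_real_, binsPerStage)
    nf <- integer(binsPerStage)
    stLab <- states[frames]
    for (b in seq_len(binsPerStage)) {
      inBin <- frames[binIdx == b]
      lab <- states[inBin]
      nRoam <- sum(lab == "roaming")
      nDwell <- sum(lab == "dwelling")
      nf[b] <- nRoam + nDwell
      if (nf[b] > 0) fr[b] <- nRoam / nf[b]
      if (nRoam > 0) sp[b] <- mean(kin@speed[inBin][lab == "roaming"])
    }
    out[[s]] <- S4Vectors::DataFrame(
      stage = factor(STAGE_NAMES[s], levels = STAGE_NAMES),
      binInStage = seq_len(binsPerStage),
      roamingFraction = fr, roamingSpeed = sp, nFrames = nf)
  }
  res <- do.call(rbind, out)
  res$bin <- seq_len(nrow(res))
  res[, c("bin", "stage", "binInStage", "roamingFraction",
          "roamingSpeed", "nFrames")]
}

#' Process one trajectory end to end
#'
#' Convenience wrapper: rolling kinematics, stage detection, classification
#' and age normalization.
#'
#' @param traj a \linkS4class{WormTrajectory}.
#' @param binsPerStage bins per stage.
#' @param cfg classifier configuration.
#' @param windowSec rolling-kinematics window (s).
#' @param seg optional precomputed \linkS4class{StageSegmentation}; detected
#'   from the data when NULL.
#' @param ... passed to \code{\link{detectStages}}.
#' @return list with \code{kinematics}, \code{segmentation}, \code{states}
#'   and \code{binned} (the \code{\link{ageNormalize}} table).
#' @export
processTrajectory <- function(traj, binsPerStage = 75L,
                              cfg = classifierConfig(), windowSec = 10,
                              seg = NULL, ...) {
  kin <- rollingKinematics(traj, windowSec = windowSec)
  if (is.null(seg)) seg <- detectStages(kin, ...)
  states <- classifyStates(kin, seg, cfg)
  binned <- ageNormalize(states, kin, seg, binsPerStage = binsPerStage)
  list(kinematics = kin, segmentation = seg, states = states,
       binned = binned)
}
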