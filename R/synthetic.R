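# Synthetic cohort, state-sequence, trajectory and frame generators. These
# define the study conditions under which the analysis machinery is validated:
# planted individuality dimensions at matrix level, and two-state locomotion
# with lethargus gaps at trajectory level.

# Per-stage baseline roaming propensity (fraction scale) used by the matrix
# generator: moderate roaming rising through mid-larval stages, lower in L1
# and adulthood.
.defaultStageBaseline <- function(nStages = 5L) {
  if (nStages == 5L) c(0.40, 0.50, 0.55, 0.50, 0.35)
  else rep(0.45, nStages)
}

#' Generate a synthetic cohort roaming matrix with planted individuality
#'
#' Each individual's per-bin roaming fraction is
#' \code{plogis(baseline_k + sqrt(K) * sum_d c[i,d] * archetype_d[k] +
#' eps[i,k])} with per-individual coefficients
#' \code{c[i,d] ~ N(0, strength_d)} and per-bin noise
#' \code{eps ~ N(0, noiseSd)}. Archetypes are unit-norm over the K bins, so
#' the \code{sqrt(K)} factor makes a strength the per-bin signal amplitude in
#' units of the per-bin noise SD (a sign-pattern archetype has entries of
#' magnitude about \code{1/sqrt(K)}). Optional per-stage stress factors
#' multiply the baseline stage roaming propensity (on the fraction scale,
#' inside the logit), so a factor of 0.3 suppresses a stage's mean roaming
#' to about 0.3 of the unstressed level. The planted coefficients
#' are returned in \code{metadata()} so recovery can be tested. One root seed
#' expands into per-individual substreams, so cohorts are reproducible.
#'
#' @param spec a \linkS4class{PopulationSpec}.
#' @param structure an \linkS4class{IndividualityStructure}; archetype length
#'   must equal \code{nStages * binsPerStageRank}.
#' @param stress optional \linkS4class{StressEffectProfile} applied to every
#'   individual (for condition-specific stress, supply a named list with one
#'   profile per condition).
#' @param baselineFraction optional numeric(nStages) of baseline stage
#'   roaming propensities (fractions); defaults to a moderate
#'   mid-development-high profile (0.40, 0.50, 0.55, 0.50, 0.35).
#' @return a \linkS4class{RoamingExperiment} with \code{binsPerStageRank}
#'   bins per stage; \code{metadata()} holds \code{planted} (individuals x
#'   archetypes coefficient matrix), \code{archetypes} and \code{seed}.
#' @examples
#' spec <- populationSpec(60, nExperiments = 2, seed = 7)
#' st <- individualityStructure("homogeneous", strengths = 1.5)
#' re <- generateRoamingMatrix(spec, st)
#' dim(roamingFraction(re))  # 50 bins x 60 individuals
#' @export
generateRoamingMatrix <- function(spec, structure, stress = NULL,
                                  baselineFraction = NULL) {
  stopifnot(is(spec, "PopulationSpec"), is(structure, "IndividualityStructure"))
  k <- spec@nStages * spec@binsPerStageRank
  if (nrow(structure@archetypes) != k)
    stop("archetype length (", nrow(structure@archetypes),
         ") does not match nStages * binsPerStageRank (", k, ")")
  n <- spec@nIndividuals
  d <- ncol(structure@archetypes)
  if (is.null(baselineFraction))
    baselineFraction <- .defaultStageBaseline(spec@nStages)
  stopifnot(length(baselineFraction) == spec@nStages,
            all(baselineFraction > 0 & baselineFraction < 1))

  condition <- rep(names(spec@conditions), spec@conditions)
  experiment <- sprintf("exp_%02d",
                        (seq_len(n) - 1L) %% spec@nExperiments + 1L)
  stageOfBin <- rep(seq_len(spec@nStages), each = spec@binsPerStageRank)

  # per-individual baseline: stress factors scale the stage propensity on the
  # fraction scale before the logit
  baseFor <- function(i) {
    prof <- if (is.null(stress)) NULL
            else if (is(stress, "StressEffectProfile")) stress
            else stress[[condition[i]]]
    f <- if (is.null(prof)) rep(1, spec@nStages) else prof@factors
    p <- pmin(pmax(baselineFraction * f, 1e-6), 1 - 1e-6)
    qlogis(p)[stageOfBin]
  }

  seeds <- .subSeeds(spec@seed, n)
  planted <- matrix(0, n, d)
  roaming <- matrix(0, k, n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    ci <- rnorm(d, 0, structure@strengths)
    eps <- rnorm(k, 0, structure@noiseSd)
    planted[i, ] <- ci
    roaming[, i] <- plogis(baseFor(i) +
                             sqrt(k) * drop(structure@archetypes %*% ci) +
                             eps)
  }
  ind <- sprintf("ind_%04d", seq_len(n))
  rownames(planted) <- ind
  colnames(planted) <- colnames(structure@archetypes)
  RoamingExperiment(roaming, experiment = experiment, condition = condition,
                    individual = ind, nStages = spec@nStages,
                    metadata = list(planted = planted,
                                    archetypes = structure@archetypes,
                                    seed = spec@seed))
}

#' Generate a two-state roam/dwell sequence for one stage
#'
#' Alternating roaming and dwelling episodes with exponential durations; the
#' starting state is drawn with the stationary probability
#' \code{roamMean / (roamMean + dwellMean)}. A zero dwelling mean yields an
#' all-roaming sequence (and vice versa).
#'
#' @param params a \linkS4class{KinematicParams}.
#' @param stage stage index 1..5.
#' @param durationSec sequence duration in seconds (> 0).
#' @param seed integer seed.
#' @return factor of per-frame labels with levels dwelling, roaming, length
#'   \code{round(durationSec * fps)}.
#' @examples
#' p <- kinematicParams()
#' s <- generateStateSequence(p, stage = 5, durationSec = 600, seed = 1)
#' mean(s == "roaming")
#' @export
generateStateSequence <- function(params, stage, durationSec, seed = 1L) {
  stopifnot(is(params, "KinematicParams"), durationSec > 0)
  fps <- params@fps
  nFrames <- round(durationSec * fps)
  rm <- params@roamDurMean[stage]
  dm <- params@dwellDurMean[stage]
  lev <- c("dwelling", "roaming")
  if (dm == 0)
    return(factor(rep("roaming", nFrames), levels = lev))
  if (rm == 0)
    return(factor(rep("dwelling", nFrames), levels = lev))
  set.seed(as.integer(seed))
  roamFirst <- runif(1) < rm / (rm + dm)
  durations <- numeric(0)
  states <- character(0)
  total <- 0
  isRoam <- roamFirst
  while (total < durationSec) {
    dur <- rexp(1, rate = 1 / if (isRoam) rm else dm)
    durations <- c(durations, dur)
    states <- c(states, if (isRoam) "roaming" else "dwelling")
    total <- total + dur
    isRoam <- !isRoam
  }
  ends <- cumsum(durations)
  frameTime <- (seq_len(nFrames) - 0.5) / fps
  factor(states[findInterval(frameTime, c(0, ends), left.open = TRUE)],
         levels = lev)
}

#' Generate a full developmental trajectory with lethargus gaps
#'
#' Builds a frame-level random-walk trajectory over five stages. Within each
#' stage, per-frame speed is drawn from the state's speed distribution
#' (truncated at zero) and the heading performs a random walk with the state's
#' heading-change SD. Between consecutive stages a lethargus span is inserted:
#' constant near-zero speed (0.3 um/s) with slow heading drift, giving the
#' stage detector unambiguous quiescence targets. The generating ground truth
#' (states, stage of every frame, true segmentation, per-stage roaming
#' fractions) is returned alongside the trajectory.
#'
#' @param params a \linkS4class{KinematicParams}.
#' @param stateSequences optional list of 5 per-stage state factors (as from
#'   \code{\link{generateStateSequence}}); generated from \code{params} and
#'   \code{seed} when NULL.
#' @param seed integer root seed (expanded into per-stage substreams).
#' @param stageDurationsH optional override of the per-stage durations (h).
#' @return list with elements \code{trajectory}
#'   (\linkS4class{WormTrajectory}), \code{states} (factor dwelling / roaming
#'   / quiescent per frame), \code{stageOfFrame}, \code{segmentation} (true
#'   \linkS4class{StageSegmentation}) and \code{perStageRoaming} (generating
#'   roaming fraction per stage).
#' @examples
#' p <- kinematicParams(stageDurationsH = rep(0.2, 5), lethargusH = 0.1)
#' g <- generateTrajectory(p, seed = 1)
#' g$trajectory
#' @export
generateTrajectory <- function(params, stateSequences = NULL, seed = 1L,
                               stageDurationsH = NULL) {
  stopifnot(is(params, "KinematicParams"))
  fps <- params@fps
  durH <- if (is.null(stageDurationsH)) params@stageDurationsH
          else rep_len(stageDurationsH, 5L)
  seeds <- .subSeeds(seed, 14L)  # 5 state streams, 5 stage streams, 4 leth
  if (is.null(stateSequences))
    stateSequences <- lapply(seq_len(5L), function(s)
      generateStateSequence(params, s, durH[s] * 3600, seed = seeds[s]))
  stopifnot(length(stateSequences) == 5L)

  nLeth <- round(params@lethargusH * 3600 * fps)
  lethStep <- 0.3 / fps  # constant near-zero displacement, um/frame

  speedFrames <- numeric(0)
  dhFrames <- numeric(0)
  stateAll <- character(0)
  stageAll <- integer(0)
  lethSpans <- matrix(integer(0), 0, 2,
                      dimnames = list(NULL, c("start", "end")))
  for (s in seq_len(5L)) {
    st <- stateSequences[[s]]
    ns <- length(st)
    set.seed(seeds[5L + s])
    roam <- st == "roaming"
    sp <- ifelse(roam,
                 rnorm(ns, params@roamSpeedMean[s], params@roamSpeedSd[s]),
                 rnorm(ns, params@dwellSpeedMean[s], params@dwellSpeedSd[s]))
    sp <- pmax(sp, 0)
    dh <- rnorm(ns, 0, ifelse(roam, params@roamHeadingSd,
                              params@dwellHeadingSd))
    speedFrames <- c(speedFrames, sp)
    dhFrames <- c(dhFrames, dh)
    stateAll <- c(stateAll, as.character(st))
    stageAll <- c(stageAll, rep(s, ns))
    if (s < 5L && nLeth > 0L) {
      set.seed(seeds[10L + s])
      start <- length(speedFrames) + 1L
      speedFrames <- c(speedFrames, rep(lethStep * fps, nLeth))
      dhFrames <- c(dhFrames, rnorm(nLeth, 0, 0.5))
      stateAll <- c(stateAll, rep("quiescent", nLeth))
      stageAll <- c(stageAll, rep(NA_integer_, nLeth))
      lethSpans <- rbind(lethSpans, c(start, start + nLeth - 1L))
    }
  }
  n <- length(speedFrames)
  heading <- cumsum(dhFrames) * pi / 180
  step <- speedFrames / fps
  # displacement into frame i uses frame i's speed and heading
  x <- cumsum(c(0, step[-1L] * cos(heading[-1L])))
  y <- cumsum(c(0, step[-1L] * sin(heading[-1L])))
  traj <- WormTrajectory(time = (seq_len(n) - 1L) / fps, x = x, y = y,
                         fps = fps)
  boundaries <- as.integer(floor((lethSpans[, 1] + lethSpans[, 2]) / 2))
  seg <- StageSegmentation(boundaries, nFrames = n,
                           lethargusSpans = lethSpans)
  perStage <- vapply(stateSequences, function(st) mean(st == "roaming"),
                     numeric(1))
  list(trajectory = traj,
       states = factor(stateAll,
                       levels = c("dwelling", "roaming", "quiescent")),
       stageOfFrame = stageAll,
       segmentation = seg,
       perStageRoaming = perStage)
}

#' Generate a cropped worm frame and its matching background
#'
#' Places a single connected blob of exactly \code{areaPx} pixels (the
#' \code{areaPx} pixels nearest the image center, an approximate disc) at
#' \code{wormLevel} on a uniform \code{backgroundLevel}, with optional
#' additive Gaussian noise. Levels are 8-bit grayscale (0-255); the worm is
#' darker than the background.
#'
#' @param areaPx blob area in pixels (0 gives a uniform background frame).
#' @param imageSide image side length in pixels (default 151).
#' @param wormLevel,backgroundLevel grayscale levels; wormLevel must be lower.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed integer seed (used only when noiseSd > 0).
#' @return list with \code{frame} and \code{background} matrices.
#' @examples
#' f <- generateWormFrame(400)
#' a <- frameArea(normalizeFrame(f$frame, f$background))
#' @export
generateWormFrame <- function(areaPx, imageSide = 151L, wormLevel = 80,
                              backgroundLevel = 160, noiseSd = 0,
                              seed = 1L) {
  stopifnot(areaPx >= 0, areaPx < imageSide^2, wormLevel < backgroundLevel)
  bg <- matrix(backgroundLevel, imageSide, imageSide)
  frame <- bg
  if (areaPx > 0) {
    ctr <- (imageSide + 1) / 2
    d2 <- outer((seq_len(imageSide) - ctr)^2,
                (seq_len(imageSide) - ctr)^2, "+")
    sel <- order(d2)[seq_len(areaPx)]
    frame[sel] <- wormLevel
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    frame <- frame + matrix(rnorm(imageSide^2, 0, noiseSd),
                            imageSide, imageSide)
  }
  list(frame = frame, background = bg)
}
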