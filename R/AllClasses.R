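#' @import methods
#' @importFrom stats median quantile rnorm rexp runif plogis qlogis var cor
#'   p.adjust wilcox.test rbinom
#' @importFrom utils read.delim write.table read.csv write.csv packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assays assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

STAGE_NAMES <- c("L1", "L2", "L3", "L4", "Adult")

#' Frame-level centroid trajectory of a single worm
#'
#' Holds the centroid time series of one individual: time in seconds and x/y
#' position in micrometers, sampled at a nominally fixed frame rate. The frame
#' index is implicit (1..length). Non-uniform sampling is tolerated at
#' construction but flagged by downstream kinematics, never silently filled.
#'
#' @slot time numeric, seconds, strictly increasing.
#' @slot x,y numeric, micrometers.
#' @slot fps nominal frames per second.
#' @export
setClass("WormTrajectory",
  representation(time = "numeric", x = "numeric", y = "numeric",
                 fps = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    if (length(object@x) != n || length(object@y) != n)
      msg <- c(msg, "time, x and y must have equal length")
    if (n > 1 && any(diff(object@time) <= 0))
      msg <- c(msg, "time must be strictly increasing")
    if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
      msg <- c(msg, "fps must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a WormTrajectory
#'
#' @param time time stamps in seconds.
#' @param x,y centroid coordinates in micrometers.
#' @param fps nominal frame rate (frames/s, default 3 as in the imaging setup).
#' @return a \linkS4class{WormTrajectory}.
#' @export
WormTrajectory <- function(time, x, y, fps = 3) {
  new("WormTrajectory", time = as.numeric(time), x = as.numeric(x),
      y = as.numeric(y), fps = as.numeric(fps))
}

#' Rolling kinematics of a trajectory
#'
#' Per-frame rolling speed (um/s) and absolute angular velocity (deg/s),
#' averaged over a centered rolling window. Edge frames whose window is
#' truncated are flagged in \code{truncated}.
#'
#' @slot speed numeric, rolling speed, um/s, >= 0.
#' @slot angularVelocity numeric, rolling |angular velocity|, deg/s, >= 0.
#' @slot windowSec rolling window length in seconds.
#' @slot fps frames per second of the source trajectory.
#' @slot truncated logical, TRUE where the rolling window was truncated.
#' @export
setClass("KinematicSeries",
  representation(speed = "numeric", angularVelocity = "numeric",
                 windowSec = "numeric", fps = "numeric",
                 truncated = "logical"),
  validity = function(object) {
    msg <- character()
    n <- length(object@speed)
    if (length(object@angularVelocity) != n || length(object@truncated) != n)
      msg <- c(msg, "speed, angularVelocity and truncated lengths differ")
    if (any(object@speed < 0, na.rm = TRUE))
      msg <- c(msg, "speed must be non-negative")
    if (any(object@angularVelocity < 0, na.rm = TRUE))
      msg <- c(msg, "angularVelocity must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Developmental stage segmentation of a recording
#'
#' Four stage boundaries at lethargus midpoints partition a recording into the
#' five stages L1-L4 and adulthood. The detected quiescent (lethargus) spans
#' are retained so classification can exclude them.
#'
#' @slot hatchFrame first frame of activity (stage L1 starts here).
#' @slot boundaries integer(4), lethargus midpoint frames, strictly increasing.
#' @slot lethargusSpans integer matrix with columns start, end (one row per
#'   detected lethargus; may have zero rows for matrix-level segmentations).
#' @slot nFrames total frames in the recording.
#' @export
setClass("StageSegmentation",
  representation(hatchFrame = "integer", boundaries = "integer",
                 lethargusSpans = "matrix", nFrames = "integer"),
  validity = function(object) {
    msg <- character()
    b <- object@boundaries
    if (length(b) != 4L)
      msg <- c(msg, "exactly 4 stage boundaries are required")
    if (any(diff(c(object@hatchFrame, b, object@nFrames)) <= 0))
      msg <- c(msg, paste("boundaries must be strictly increasing and",
                          "interior to the recording"))
    if (ncol(object@lethargusSpans) != 2L)
      msg <- c(msg, "lethargusSpans must have columns start, end")
    if (length(msg)) msg else TRUE
  })

#' Construct a StageSegmentation
#'
#' @param boundaries four lethargus-midpoint frames (increasing).
#' @param nFrames total number of frames.
#' @param hatchFrame first active frame (default 1).
#' @param lethargusSpans optional integer matrix (start, end) of quiescent
#'   spans; defaults to zero-width spans at the boundaries.
#' @return a \linkS4class{StageSegmentation}.
#' @export
StageSegmentation <- function(boundaries, nFrames, hatchFrame = 1L,
                              lethargusSpans = NULL) {
  boundaries <- as.integer(boundaries)
  if (is.null(lethargusSpans))
    lethargusSpans <- cbind(start = boundaries, end = boundaries)
  lethargusSpans <- matrix(as.integer(lethargusSpans),
                           ncol = 2L, dimnames = list(NULL, c("start", "end")))
  new("StageSegmentation", hatchFrame = as.integer(hatchFrame),
      boundaries = boundaries, lethargusSpans = lethargusSpans,
      nFrames = as.integer(nFrames))
}

#' Roaming/dwelling diagonal classifier configuration
#'
#' The two-state classifier works in histogram-bin units: speed divided by its
#' bin width and angular velocity divided by its bin width. A frame is roaming
#' when its speed (bin units) exceeds the stage slope times its angular
#' velocity (bin units); on-diagonal frames and frames in the zeroth speed bin
#' are dwelling.
#'
#' @slot speedBinWidth um/s per histogram bin (default 7.59).
#' @slot angularBinWidth deg/s per histogram bin (default 3.6).
#' @slot slopes named numeric(5), diagonal slope per stage
#'   (defaults 5, 2.5, 2.3, 2, 1.5 for L1, L2, L3, L4, Adult).
#' @slot histogramBins bins per axis of the reference 2-D histogram (50).
#' @export
setClass("ClassifierConfig",
  representation(speedBinWidth = "numeric", angularBinWidth = "numeric",
                 slopes = "numeric", histogramBins = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@speedBinWidth <= 0 || object@angularBinWidth <= 0)
      msg <- c(msg, "bin widths must be positive")
    if (length(object@slopes) != 5L || is.null(names(object@slopes)) ||
        !identical(names(object@slopes), STAGE_NAMES))
      msg <- c(msg, "slopes must be a numeric(5) named L1, L2, L3, L4, Adult")
    if (length(msg)) msg else TRUE
  })

#' Construct a ClassifierConfig
#'
#' @param speedBinWidth,angularBinWidth histogram bin widths (um/s, deg/s).
#' @param slopes per-stage diagonal slopes (L1, L2, L3, L4, Adult).
#' @param histogramBins reference histogram size per axis.
#' @return a \linkS4class{ClassifierConfig}.
#' @examples
#' cfg <- classifierConfig()
#' slopes(cfg)
#' @export
classifierConfig <- function(speedBinWidth = 7.59, angularBinWidth = 3.6,
                             slopes = c(L1 = 5, L2 = 2.5, L3 = 2.3,
                                        L4 = 2, Adult = 1.5),
                             histogramBins = 50L) {
  if (is.null(names(slopes)) && length(slopes) == 5L)
    names(slopes) <- STAGE_NAMES
  new("ClassifierConfig", speedBinWidth = speedBinWidth,
      angularBinWidth = angularBinWidth, slopes = slopes,
      histogramBins = as.integer(histogramBins))
}

#' Cohort container for binned roaming behavior
#'
#' A \linkS4class{SummarizedExperiment} whose rows are age-normalized time bins
#' (rowData: \code{stage}, \code{binInStage}) and whose columns are individual
#' worms (colData: \code{individual}, \code{experiment}, \code{condition}).
#' The \code{"roaming"} assay holds per-bin roaming fractions in [0, 1];
#' \code{\link{rankIndividuals}} and \code{\link{biasTransform}} add
#' \code{"rank"} and \code{"bias"} assays.
#'
#' @export
setClass("RoamingExperiment", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object)
    need <- c("individual", "experiment", "condition")
    if (!all(need %in% colnames(cd)))
      msg <- c(msg, paste("colData must contain",
                          paste(need, collapse = ", ")))
    if (!"stage" %in% colnames(SummarizedExperiment::rowData(object)))
      msg <- c(msg, "rowData must contain stage")
    if ("roaming" %in% SummarizedExperiment::assayNames(object)) {
      r <- SummarizedExperiment::assay(object, "roaming")
      if (any(r < 0 | r > 1, na.rm = TRUE))
        msg <- c(msg, "roaming fractions must lie in [0, 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a RoamingExperiment
#'
#' @param roaming numeric matrix of roaming fractions, time bins x individuals
#'   (a bins-in-rows orientation; transpose an individuals x bins matrix).
#' @param experiment character/factor, experiment label per individual.
#' @param condition character/factor, condition label per individual.
#' @param individual individual identifiers (default \code{ind_####}).
#' @param nStages number of developmental stages the bins span (default 5).
#' @param metadata optional list stored in \code{metadata()}.
#' @return a \linkS4class{RoamingExperiment}.
#' @examples
#' m <- matrix(runif(50 * 8), nrow = 50)
#' re <- RoamingExperiment(m, experiment = rep("e1", 8),
#'                         condition = rep("ctrl", 8))
#' binsPerStage(re)
#' @export
RoamingExperiment <- function(roaming, experiment, condition,
                              individual = NULL, nStages = 5L,
                              metadata = list()) {
  roaming <- as.matrix(roaming)
  n <- ncol(roaming)
  if (is.null(individual))
    individual <- sprintf("ind_%04d", seq_len(n))
  k <- nrow(roaming)
  if (k %% nStages != 0L)
    stop("number of bins (", k, ") is not a multiple of nStages (",
         nStages, ")")
  bps <- k %/% nStages
  rowData <- S4Vectors::DataFrame(
    stage = factor(rep(STAGE_NAMES[seq_len(nStages)], each = bps),
                   levels = STAGE_NAMES[seq_len(nStages)]),
    binInStage = rep(seq_len(bps), nStages))
  colData <- S4Vectors::DataFrame(individual = as.character(individual),
                                  experiment = as.character(experiment),
                                  condition = as.character(condition),
                                  row.names = as.character(individual))
  dimnames(roaming) <- list(sprintf("bin_%03d", seq_len(k)),
                            as.character(individual))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(roaming = roaming), rowData = rowData, colData = colData,
    metadata = metadata)
  new("RoamingExperiment", se)
}

#' Weighted-covariance PCA of a bias matrix
#'
#' Decomposition of the per-individual bias vectors into individuality
#' dimensions: unit-norm components over time bins, per-individual scores, and
#' the eigenvalues of the weighted second-moment matrix (individuals weighted
#' inversely to their condition size so every condition contributes equally).
#'
#' @slot components bins x bins matrix, one unit-norm component per column,
#'   in descending eigenvalue order; sign fixed so the largest-magnitude entry
#'   of each component is positive.
#' @slot eigenvalues eigenvalues of the weighted second-moment matrix.
#' @slot scores individuals x bins matrix of projections (scores).
#' @slot weights per-individual weights used (1 / condition size).
#' @slot conditions condition label per individual.
#' @slot centered logical, whether a weighted mean was subtracted (default
#'   FALSE: per-bin biases average to zero by construction).
#' @export
setClass("BiasPCA",
  representation(components = "matrix", eigenvalues = "numeric",
                 scores = "matrix", weights = "numeric",
                 conditions = "character", centered = "logical"),
  validity = function(object) {
    msg <- character()
    k <- ncol(object@components)
    if (length(object@eigenvalues) != k || ncol(object@scores) != k)
      msg <- c(msg, "components, eigenvalues and scores dimensions disagree")
    if (nrow(object@scores) != length(object@weights) ||
        nrow(object@scores) != length(object@conditions))
      msg <- c(msg, "one weight and condition per individual is required")
    if (is.unsorted(rev(object@eigenvalues), strictly = FALSE) &&
        any(diff(object@eigenvalues) > 1e-8 * max(abs(object@eigenvalues))))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (length(msg)) msg else TRUE
  })

# ---- generative parameter classes -------------------------------------------

#' Cohort layout for the synthetic generator
#'
#' @slot nIndividuals number of individuals in the cohort.
#' @slot nExperiments number of experiments; individuals are assigned
#'   round-robin so experiments have near-equal size.
#' @slot conditions named integer, per-condition individual counts (must sum
#'   to \code{nIndividuals}).
#' @slot nStages number of developmental stages (default 5).
#' @slot binsPerStageFine fine time bins per stage (default 75).
#' @slot binsPerStageRank rank time bins per stage (default 10).
#' @slot seed integer root seed.
#' @export
setClass("PopulationSpec",
  representation(nIndividuals = "integer", nExperiments = "integer",
                 conditions = "integer", nStages = "integer",
                 binsPerStageFine = "integer", binsPerStageRank = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nIndividuals < 1L || object@nExperiments < 1L ||
        object@nStages < 1L || object@binsPerStageFine < 1L ||
        object@binsPerStageRank < 1L)
      msg <- c(msg, "all counts must be positive")
    if (any(object@conditions < 1L))
      msg <- c(msg, "per-condition counts must be positive")
    if (sum(object@conditions) != object@nIndividuals)
      msg <- c(msg, "per-condition counts must sum to nIndividuals")
    if (is.null(names(object@conditions)))
      msg <- c(msg, "conditions must be named")
    if (length(msg)) msg else TRUE
  })

#' Construct a PopulationSpec
#'
#' @param nIndividuals cohort size.
#' @param nExperiments number of experiments (round-robin assignment).
#' @param conditions named integer vector of per-condition counts; default one
#'   condition \code{"ctrl"} covering the whole cohort.
#' @param nStages,binsPerStageFine,binsPerStageRank binning layout.
#' @param seed integer root seed.
#' @return a \linkS4class{PopulationSpec}.
#' @examples
#' populationSpec(456, nExperiments = 4, seed = 1)
#' @export
populationSpec <- function(nIndividuals, nExperiments = 1L,
                           conditions = NULL, nStages = 5L,
                           binsPerStageFine = 75L, binsPerStageRank = 10L,
                           seed = 1L) {
  if (is.null(conditions))
    conditions <- c(ctrl = as.integer(nIndividuals))
  new("PopulationSpec", nIndividuals = as.integer(nIndividuals),
      nExperiments = as.integer(nExperiments),
      conditions = structure(as.integer(conditions),
                             names = names(conditions)),
      nStages = as.integer(nStages),
      binsPerStageFine = as.integer(binsPerStageFine),
      binsPerStageRank = as.integer(binsPerStageRank),
      seed = as.integer(seed))
}

#' Planted individuality structure for the synthetic generator
#'
#' Archetypes are unit-norm loading patterns over the rank time bins;
#' per-individual coefficients along each archetype are drawn with the given
#' strengths (SD, relative to the per-bin noise SD). Built-in archetypes:
#' \code{"homogeneous"} (constant sign: consistent individuals),
#' \code{"single_switch"} (sign flip at the L3 midpoint) and
#' \code{"double_switch"} (sign flips at the L1/L2 and L4/Adult boundaries).
#' Archetypes are orthonormalized (Gram-Schmidt, in order) at construction.
#'
#' @slot archetypes bins x dimensions matrix of orthonormal loadings.
#' @slot strengths per-archetype coefficient SD (>= 0).
#' @slot noiseSd per-bin iid noise SD.
#' @export
setClass("IndividualityStructure",
  representation(archetypes = "matrix", strengths = "numeric",
                 noiseSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@archetypes) != length(object@strengths))
      msg <- c(msg, "one strength per archetype is required")
    if (any(object@strengths < 0))
      msg <- c(msg, "strengths must be non-negative")
    if (object@noiseSd < 0)
      msg <- c(msg, "noiseSd must be non-negative")
    g <- crossprod(object@archetypes)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
      msg <- c(msg, "archetypes must be orthonormal")
    if (length(msg)) msg else TRUE
  })

#' Construct an IndividualityStructure
#'
#' @param archetypes character vector naming built-ins (any of
#'   \code{"homogeneous"}, \code{"single_switch"}, \code{"double_switch"}) or
#'   a numeric matrix of loading patterns (bins x dimensions).
#' @param strengths per-archetype coefficient SD.
#' @param noiseSd per-bin noise SD (default 1).
#' @param nStages,binsPerStage layout used to build the built-in patterns.
#' @return an \linkS4class{IndividualityStructure}.
#' @examples
#' individualityStructure("homogeneous", strengths = 1.5)
#' @export
individualityStructure <- function(archetypes = "homogeneous",
                                   strengths = 1, noiseSd = 1,
                                   nStages = 5L, binsPerStage = 10L) {
  if (is.character(archetypes)) {
    k <- nStages * binsPerStage
    build <- function(name) {
      switch(name,
        homogeneous = rep(1, k),
        # flip at the midpoint of the middle (L3) stage
        single_switch = {
          v <- rep(1, k)
          v[seq_len(k) > k / 2] <- -1
          v
        },
        # flips at the L1/L2 and L4/Adult stage boundaries
        double_switch = {
          v <- rep(-1, k)
          v[seq_len(k) <= binsPerStage] <- 1
          v[seq_len(k) > (nStages - 1L) * binsPerStage] <- 1
          v
        },
        stop("unknown archetype: ", name))
    }
    archetypes <- vapply(archetypes, build, numeric(nStages * binsPerStage))
  }
  archetypes <- as.matrix(archetypes)
  # Gram-Schmidt in the given order, then unit norm
  for (j in seq_len(ncol(archetypes))) {
    v <- archetypes[, j]
    if (j > 1L) {
      prev <- archetypes[, seq_len(j - 1L), drop = FALSE]
      v <- v - prev %*% crossprod(prev, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12)
      stop("archetype ", j, " is linearly dependent on earlier archetypes")
    archetypes[, j] <- v / nv
  }
  new("IndividualityStructure", archetypes = archetypes,
      strengths = as.numeric(strengths), noiseSd = as.numeric(noiseSd))
}

#' Per-stage stress effect profile
#'
#' Multiplicative factors applied to the pre-logistic per-stage baseline
#' offset of roaming propensity. The default mimics a strong early-stress
#' response: suppression in L1 and adulthood, buffering (factor ~1) in the
#' intermediate stages.
#'
#' @slot factors numeric(nStages), >= 0.
#' @slot label free-text description.
#' @export
setClass("StressEffectProfile",
  representation(factors = "numeric", label = "character"),
  validity = function(object) {
    if (any(object@factors < 0)) "factors must be non-negative" else TRUE
  })

#' Construct a StressEffectProfile
#'
#' @param factors per-stage multiplicative factors on the baseline offset.
#' @param label description.
#' @return a \linkS4class{StressEffectProfile}.
#' @examples
#' stressProfile()  # wild-type-like: suppressed L1/Adult, buffered L2-L4
#' @export
stressProfile <- function(factors = c(0.3, 1, 1, 1, 0.3),
                          label = "wild-type-like") {
  new("StressEffectProfile", factors = as.numeric(factors), label = label)
}

#' Kinematic parameters for the trajectory generator
#'
#' Per-stage two-state locomotion parameters. Roaming is fast and straight
#' (low heading change); dwelling is slow with frequent reorientations.
#' Episode durations are exponential with the given means. Defaults are
#' fixtures chosen to be realistic for C. elegans on food, not estimates
#' fitted to recordings.
#'
#' @slot fps frames per second (default 3).
#' @slot roamSpeedMean,roamSpeedSd per-stage roaming speed (um/s).
#' @slot dwellSpeedMean,dwellSpeedSd per-stage dwelling speed (um/s).
#' @slot roamHeadingSd,dwellHeadingSd heading-change SD (deg per frame).
#' @slot roamDurMean,dwellDurMean per-stage mean episode durations (s).
#' @slot stageDurationsH per-stage durations (h).
#' @slot lethargusH lethargus duration between stages (h).
#' @export
setClass("KinematicParams",
  representation(fps = "numeric",
                 roamSpeedMean = "numeric", roamSpeedSd = "numeric",
                 dwellSpeedMean = "numeric", dwellSpeedSd = "numeric",
                 roamHeadingSd = "numeric", dwellHeadingSd = "numeric",
                 roamDurMean = "numeric", dwellDurMean = "numeric",
                 stageDurationsH = "numeric", lethargusH = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@fps <= 0) msg <- c(msg, "fps must be positive")
    if (any(c(object@roamSpeedMean, object@dwellSpeedMean,
              object@stageDurationsH, object@lethargusH) <= 0))
      msg <- c(msg, "speeds and durations must be positive")
    if (any(object@roamSpeedMean <= object@dwellSpeedMean))
      msg <- c(msg, "roam speed mean must exceed dwell speed mean per stage")
    if (any(c(object@roamDurMean, object@dwellDurMean) < 0))
      msg <- c(msg, "episode duration means must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Construct KinematicParams
#'
#' @param fps frames per second.
#' @param roamSpeedMean,roamSpeedSd,dwellSpeedMean,dwellSpeedSd per-stage
#'   speed distributions (um/s); scalars are recycled to 5 stages.
#' @param roamHeadingSd,dwellHeadingSd heading-change SD (deg/frame).
#' @param roamDurMean,dwellDurMean mean episode durations (s).
#' @param stageDurationsH per-stage durations (h).
#' @param lethargusH lethargus duration (h).
#' @return a \linkS4class{KinematicParams}.
#' @export
kinematicParams <- function(fps = 3,
                            roamSpeedMean = c(80, 110, 130, 150, 170),
                            roamSpeedSd = 15,
                            dwellSpeedMean = c(6, 8, 10, 12, 15),
                            dwellSpeedSd = 3,
                            roamHeadingSd = 2, dwellHeadingSd = 40,
                            roamDurMean = 90, dwellDurMean = 135,
                            stageDurationsH = c(12, 8, 8, 10, 16),
                            lethargusH = 0.5) {
  r5 <- function(x) rep_len(as.numeric(x), 5L)
  new("KinematicParams", fps = fps,
      roamSpeedMean = r5(roamSpeedMean), roamSpeedSd = r5(roamSpeedSd),
      dwellSpeedMean = r5(dwellSpeedMean), dwellSpeedSd = r5(dwellSpeedSd),
      roamHeadingSd = as.numeric(roamHeadingSd),
      dwellHeadingSd = as.numeric(dwellHeadingSd),
      roamDurMean = r5(roamDurMean), dwellDurMean = r5(dwellDurMean),
      stageDurationsH = r5(stageDurationsH),
      lethargusH = as.numeric(lethargusH))
}
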