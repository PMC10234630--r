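# Accessor generics and show methods for the core classes.

#' @rdname WormTrajectory-class
#' @param object,x a package object.
#' @export
setGeneric("fps", function(x) standardGeneric("fps"))

#' @rdname WormTrajectory-class
#' @export
setMethod("fps", "WormTrajectory", function(x) x@fps)

#' @rdname KinematicSeries-class
#' @export
setMethod("fps", "KinematicSeries", function(x) x@fps)

#' @rdname KinematicSeries-class
#' @param x a \linkS4class{KinematicSeries}.
#' @export
setGeneric("speed", function(x) standardGeneric("speed"))

#' @rdname KinematicSeries-class
#' @export
setMethod("speed", "KinematicSeries", function(x) x@speed)

#' @rdname KinematicSeries-class
#' @export
setGeneric("angularVelocity", function(x) standardGeneric("angularVelocity"))

#' @rdname KinematicSeries-class
#' @export
setMethod("angularVelocity", "KinematicSeries", function(x) x@angularVelocity)

#' @rdname StageSegmentation-class
#' @param x a \linkS4class{StageSegmentation}.
#' @export
setGeneric("stageBoundaries", function(x) standardGeneric("stageBoundaries"))

#' @rdname StageSegmentation-class
#' @export
setMethod("stageBoundaries", "StageSegmentation", function(x) x@boundaries)

#' @rdname StageSegmentation-class
#' @export
setGeneric("lethargusSpans", function(x) standardGeneric("lethargusSpans"))

#' @rdname StageSegmentation-class
#' @export
setMethod("lethargusSpans", "StageSegmentation", function(x) x@lethargusSpans)

#' Stage label of every frame
#'
#' Maps frames 1..nFrames to the five stages using the lethargus-midpoint
#' boundaries; frames before the hatch frame are NA.
#'
#' @param x a \linkS4class{StageSegmentation}.
#' @return factor of length nFrames with levels L1..Adult.
#' @export
setGeneric("stageOfFrame", function(x) standardGeneric("stageOfFrame"))

#' @rdname stageOfFrame
#' @export
setMethod("stageOfFrame", "StageSegmentation", function(x) {
  frames <- seq_len(x@nFrames)
  idx <- findInterval(frames, c(x@hatchFrame, x@boundaries + 1L))
  out <- factor(STAGE_NAMES[ifelse(idx >= 1L & idx <= 5L, idx, NA)],
                levels = STAGE_NAMES)
  out
})

#' @rdname ClassifierConfig-class
#' @param x a \linkS4class{ClassifierConfig}.
#' @export
setGeneric("slopes", function(x) standardGeneric("slopes"))

#' @rdname ClassifierConfig-class
#' @export
setMethod("slopes", "ClassifierConfig", function(x) x@slopes)

#' @rdname RoamingExperiment
#' @param x a \linkS4class{RoamingExperiment}.
#' @export
setGeneric("roamingFraction", function(x) standardGeneric("roamingFraction"))

#' @rdname RoamingExperiment
#' @export
setMethod("roamingFraction", "RoamingExperiment", function(x)
  SummarizedExperiment::assay(x, "roaming"))

#' @rdname RoamingExperiment
#' @export
setGeneric("rankValues", function(x) standardGeneric("rankValues"))

#' @rdname RoamingExperiment
#' @export
setMethod("rankValues", "RoamingExperiment", function(x) {
  if (!"rank" %in% SummarizedExperiment::assayNames(x))
    stop("no rank assay; run rankIndividuals() first")
  SummarizedExperiment::assay(x, "rank")
})

#' @rdname RoamingExperiment
#' @export
setGeneric("biasValues", function(x) standardGeneric("biasValues"))

#' @rdname RoamingExperiment
#' @export
setMethod("biasValues", "RoamingExperiment", function(x) {
  if (!"bias" %in% SummarizedExperiment::assayNames(x))
    stop("no bias assay; run biasTransform() first")
  SummarizedExperiment::assay(x, "bias")
})

#' @rdname RoamingExperiment
#' @export
setGeneric("experimentLabels", function(x) standardGeneric("experimentLabels"))

#' @rdname RoamingExperiment
#' @export
setMethod("experimentLabels", "RoamingExperiment", function(x)
  SummarizedExperiment::colData(x)$experiment)

#' @rdname RoamingExperiment
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname RoamingExperiment
#' @export
setMethod("conditionLabels", "RoamingExperiment", function(x)
  SummarizedExperiment::colData(x)$condition)

#' @rdname RoamingExperiment
#' @export
setGeneric("binStage", function(x) standardGeneric("binStage"))

#' @rdname RoamingExperiment
#' @export
setMethod("binStage", "RoamingExperiment", function(x)
  SummarizedExperiment::rowData(x)$stage)

#' @rdname RoamingExperiment
#' @export
setGeneric("binsPerStage", function(x) standardGeneric("binsPerStage"))

#' @rdname RoamingExperiment
#' @export
setMethod("binsPerStage", "RoamingExperiment", function(x)
  as.integer(nrow(x) / nlevels(droplevels(binStage(x)))))

#' @rdname BiasPCA-class
#' @param x a \linkS4class{BiasPCA}.
#' @export
setGeneric("pcComponents", function(x) standardGeneric("pcComponents"))

#' @rdname BiasPCA-class
#' @export
setMethod("pcComponents", "BiasPCA", function(x) x@components)

#' @rdname BiasPCA-class
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))

#' @rdname BiasPCA-class
#' @export
setMethod("pcScores", "BiasPCA", function(x) x@scores)

#' Explained variance of each individuality dimension
#'
#' @param x a \linkS4class{BiasPCA}.
#' @param proportion if TRUE (default) return the fraction of total weighted
#'   variance; otherwise the raw eigenvalues.
#' @return numeric vector, one entry per component.
#' @export
setGeneric("explainedVariance",
           function(x, proportion = TRUE) standardGeneric("explainedVariance"))

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "BiasPCA", function(x, proportion = TRUE) {
  if (proportion) x@eigenvalues / sum(x@eigenvalues) else x@eigenvalues
})

# ---- show methods -----------------------------------------------------------

setMethod("show", "WormTrajectory", function(object) {
  n <- length(object@time)
  cat("WormTrajectory:", n, "frames at", object@fps, "fps (",
      if (n) sprintf("%.2f", (object@time[n] - object@time[1]) / 3600)
      else 0, "h )\n")
})

setMethod("show", "KinematicSeries", function(object) {
  cat("KinematicSeries:", length(object@speed), "frames,",
      object@windowSec, "s rolling window\n",
      sprintf("  speed %.1f-%.1f um/s, |angular velocity| %.1f-%.1f deg/s\n",
              min(object@speed), max(object@speed),
              min(object@angularVelocity), max(object@angularVelocity)))
})

setMethod("show", "StageSegmentation", function(object) {
  cat("StageSegmentation:", object@nFrames, "frames; boundaries at",
      paste(object@boundaries, collapse = ", "), "\n")
})

setMethod("show", "BiasPCA", function(object) {
  ev <- explainedVariance(object)
  cat("BiasPCA:", nrow(object@scores), "individuals,",
      ncol(object@components), "bins;",
      length(unique(object@conditions)), "condition(s)\n",
      "  top explained variance:",
      paste(sprintf("%.1f%%", 100 * ev[seq_len(min(3, length(ev)))]),
            collapse = ", "), "\n")
})

setMethod("show", "PopulationSpec", function(object) {
  cat("PopulationSpec:", object@nIndividuals, "individuals in",
      object@nExperiments, "experiment(s),",
      length(object@conditions), "condition(s); seed", object@seed, "\n")
})
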