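# Plain-text readers and writers, plus the end-to-end pipeline driver.

#' Read and write trajectory TSV files
#'
#' The trajectory format has columns \code{frame}, \code{time_s},
#' \code{x_um}, \code{y_um}.
#'
#' @param path file path.
#' @param fps frame rate; inferred from the time stamps when NULL.
#' @return \code{readTrajectoryTSV}: a \linkS4class{WormTrajectory}.
#' @export
readTrajectoryTSV <- function(path, fps = NULL) {
  d <- read.delim(path)
  need <- c("frame", "time_s", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("trajectory TSV must have columns ", paste(need, collapse = ", "))
  if (is.null(fps)) fps <- 1 / median(diff(d$time_s))
  WormTrajectory(time = d$time_s, x = d$x_um, y = d$y_um, fps = fps)
}

#' @rdname readTrajectoryTSV
#' @param traj a \linkS4class{WormTrajectory}.
#' @export
writeTrajectoryTSV <- function(traj, path) {
  d <- data.frame(frame = seq_along(traj@time), time_s = traj@time,
                  x_um = traj@x, y_um = traj@y)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cohort roaming matrices as CSV
#'
#' The matrix CSV has one row per individual and one column per bin (header
#' row of bin labels); the adjoining labels CSV has columns
#' \code{individual_id}, \code{experiment_id}, \code{condition}.
#'
#' @param path matrix CSV path.
#' @param labelsPath labels CSV path.
#' @param nStages stage count (default 5).
#' @return \code{readRoamingCSV}: a \linkS4class{RoamingExperiment}.
#' @export
readRoamingCSV <- function(path, labelsPath, nStages = 5L) {
  m <- as.matrix(read.csv(path, row.names = 1L, check.names = FALSE))
  lab <- read.csv(labelsPath)
  need <- c("individual_id", "experiment_id", "condition")
  if (!all(need %in% names(lab)))
    stop("labels CSV must have columns ", paste(need, collapse = ", "))
  ord <- match(rownames(m), lab$individual_id)
  if (anyNA(ord)) stop("labels CSV does not cover all individuals")
  RoamingExperiment(t(m), experiment = lab$experiment_id[ord],
                    condition = lab$condition[ord],
                    individual = rownames(m), nStages = nStages)
}

#' @rdname readRoamingCSV
#' @param re a \linkS4class{RoamingExperiment}.
#' @export
writeRoamingCSV <- function(re, path, labelsPath) {
  m <- t(roamingFraction(re))
  write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  lab <- data.frame(individual_id = colnames(roamingFraction(re)),
                    experiment_id = experimentLabels(re),
                    condition = conditionLabels(re))
  write.csv(lab, labelsPath, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a BiasPCA model as JSON
#'
#' Components, eigenvalues, scores, weights and conditions round-trip
#' losslessly (full double precision).
#'
#' @param model a \linkS4class{BiasPCA}.
#' @param path JSON path.
#' @export
writePCAJSON <- function(model, path) {
  obj <- list(components = model@components,
              eigenvalues = model@eigenvalues,
              scores = model@scores,
              scoreIds = rownames(model@scores),
              weights = model@weights,
              conditions = model@conditions,
              centered = model@centered)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writePCAJSON
#' @export
readPCAJSON <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  comp <- as.matrix(o$components)
  colnames(comp) <- paste0("PC", seq_len(ncol(comp)))
  scores <- as.matrix(o$scores)
  dimnames(scores) <- list(o$scoreIds, colnames(comp))
  new("BiasPCA", components = comp, eigenvalues = as.numeric(o$eigenvalues),
      scores = scores, weights = as.numeric(o$weights),
      conditions = as.character(o$conditions),
      centered = isTRUE(o$centered))
}

# validate a pipeline config before any computation
.validateRunConfig <- function(config) {
  defaults <- list(seed = 1L, level = "matrix",
                   nIndividuals = 120L, nExperiments = 4L,
                   conditions = NULL,
                   archetypes = c("homogeneous", "single_switch",
                                  "double_switch"),
                   strengths = c(1.5, 1.0, 0.7), noiseSd = 1,
                   binsPerStageRank = 10L, binsPerStageFine = 75L,
                   classifier = classifierConfig(),
                   stageDurationsH = rep(0.2, 5), lethargusH = 0.1,
                   nReps = 100L, nPerm = 1000L, alpha = 0.05, fdr = 0.05,
                   outDir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  config <- modifyList(defaults, config)
  if (!config$level %in% c("matrix", "trajectory"))
    stop("level must be 'matrix' or 'trajectory'")
  cfg <- config$classifier
  if (!is(cfg, "ClassifierConfig")) {
    if (is.null(cfg$slopes) || length(cfg$slopes) != 5L)
      stop("classifier config must provide 5 per-stage slopes")
    config$classifier <- classifierConfig(
      speedBinWidth = cfg$speedBinWidth %||% 7.59,
      angularBinWidth = cfg$angularBinWidth %||% 3.6,
      slopes = cfg$slopes)
  }
  if (config$nReps < 1L) stop("nReps must be at least 1")
  if (length(config$strengths) != length(config$archetypes))
    stop("one strength per archetype is required")
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic-cohort analysis pipeline
#'
#' Deterministic end-to-end run from one root seed: generate a synthetic
#' cohort (at matrix level, or at trajectory level with per-individual
#' trajectory processing), rank, bias-transform, fit the weighted PCA, test
#' component significance against shuffle nulls, compute the consistency
#' index and stage-level summaries, and assemble a manifest of every result
#' with the parameters used. The configuration is validated before any
#' computation.
#'
#' @param config named list; recognized fields (all defaulted): \code{seed},
#'   \code{level} ("matrix" or "trajectory"), \code{nIndividuals},
#'   \code{nExperiments}, \code{conditions}, \code{archetypes},
#'   \code{strengths}, \code{noiseSd}, \code{binsPerStageRank},
#'   \code{binsPerStageFine}, \code{classifier}, \code{stageDurationsH},
#'   \code{lethargusH}, \code{nReps}, \code{nPerm}, \code{alpha},
#'   \code{fdr}, \code{outDir} (write CSV/JSON outputs there when set).
#' @return list with \code{experiment} (the rank/bias-annotated
#'   \linkS4class{RoamingExperiment}), \code{pca}, \code{significance},
#'   \code{consistency}, \code{stageSummary} and \code{manifest}.
#' @export
runPipeline <- function(config = list()) {
  config <- .validateRunConfig(config)
  spec <- populationSpec(config$nIndividuals,
                         nExperiments = config$nExperiments,
                         conditions = config$conditions,
                         binsPerStageFine = config$binsPerStageFine,
                         binsPerStageRank = config$binsPerStageRank,
                         seed = config$seed)
  structure <- individualityStructure(config$archetypes,
                                      strengths = config$strengths,
                                      noiseSd = config$noiseSd,
                                      binsPerStage = config$binsPerStageRank)
  if (config$level == "matrix") {
    re <- generateRoamingMatrix(spec, structure)
  } else {
    params <- kinematicParams(stageDurationsH = config$stageDurationsH,
                              lethargusH = config$lethargusH)
    seeds <- .subSeeds(config$seed, config$nIndividuals)
    mats <- vapply(seq_len(config$nIndividuals), function(i) {
      g <- generateTrajectory(params, seed = seeds[i])
      pr <- processTrajectory(g$trajectory, cfg = config$classifier,
                              binsPerStage = config$binsPerStageRank)
      pr$binned$roamingFraction
    }, numeric(5L * config$binsPerStageRank))
    cond <- if (is.null(config$conditions)) c(ctrl = config$nIndividuals)
            else config$conditions
    re <- RoamingExperiment(
      mats,
      experiment = sprintf("exp_%02d", (seq_len(config$nIndividuals) - 1L)
                           %% config$nExperiments + 1L),
      condition = rep(names(cond), cond))
  }
  re <- biasTransform(rankIndividuals(re))
  pca <- weightedPCA(re)
  sig <- pcSignificance(re, nReps = config$nReps, alpha = config$alpha,
                        seed = config$seed)
  ci <- consistencyIndex(re)
  sm <- stageMeans(re)
  manifest <- list(
    package = as.character(packageVersion("roamdev")),
    seed = config$seed, level = config$level,
    nIndividuals = config$nIndividuals, nReps = config$nReps,
    alpha = config$alpha,
    outputs = c("experiment", "pca", "significance", "consistency",
                "stageSummary"))
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeRoamingCSV(re, file.path(config$outDir, "roaming.csv"),
                    file.path(config$outDir, "labels.csv"))
    writePCAJSON(pca, file.path(config$outDir, "pca.json"))
    write.csv(as.data.frame(sig), file.path(config$outDir,
                                            "significance.csv"),
              row.names = FALSE)
    write.csv(data.frame(individual = names(ci), consistency = ci),
              file.path(config$outDir, "consistency.csv"),
              row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(experiment = re, pca = pca, significance = sig, consistency = ci,
       stageSummary = sm, manifest = manifest)
}
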