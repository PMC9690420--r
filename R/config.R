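## Experiment-level configuration: a single YAML-serializable tree tying
## together the generator, loss weights, acquisition and loop settings.

#' Experiment configuration
#'
#' Bundles every tunable of a full run into one serializable object; all
#' randomness of a run traces back to the seeds recorded here.
#'
#' @param synthetic a \code{\link{syntheticConfig}}.
#' @param weights a \code{\link{lossWeights}}.
#' @param loop a \code{\link{loopConfig}} (carries the
#'   \code{\link{acquisitionConfig}}).
#' @param outputDir directory where run artifacts are written.
#' @param trainRatio train share of the stratified split (default 0.7).
#' @return a list of class \code{experimentConfig}.
#' @export
experimentConfig <- function(synthetic = syntheticConfig(),
                             weights = lossWeights(),
                             loop = loopConfig(),
                             outputDir = "patchal-run",
                             trainRatio = 0.7) {
  structure(list(synthetic = synthetic, weights = weights, loop = loop,
                 outputDir = outputDir, trainRatio = trainRatio),
            class = "experimentConfig")
}

#' Serialize an experiment configuration to YAML
#' @param config an \code{\link{experimentConfig}}.
#' @param path output file path.
#' @export
writeExperimentConfig <- function(config, path) {
  stopifnot(inherits(config, "experimentConfig"))
  flat <- list(
    synthetic = unclass(config$synthetic),
    weights = unclass(config$weights),
    loop = c(unclass(config$loop)[setdiff(names(config$loop),
                                          c("acquisition", "weights"))],
             list(acquisition = unclass(config$loop$acquisition))),
    outputDir = config$outputDir,
    trainRatio = config$trainRatio)
  ## Inf is not a YAML 1.1 literal yaml::yaml.load understands reliably;
  ## encode an unlimited budget as -1.
  if (is.infinite(flat$loop$labelBudget)) flat$loop$labelBudget <- -1
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read an experiment configuration from YAML
#'
#' Round trip: \code{readExperimentConfig(writeExperimentConfig(x))} equals
#' \code{x}.
#'
#' @param path YAML file written by \code{\link{writeExperimentConfig}}.
#' @return an \code{\link{experimentConfig}}.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  budget <- y$loop$labelBudget
  if (!is.null(budget) && budget < 0) budget <- Inf
  experimentConfig(
    synthetic = do.call(syntheticConfig, y$synthetic),
    weights = do.call(lossWeights, y$weights),
    loop = do.call(loopConfig, c(
      y$loop[setdiff(names(y$loop), c("acquisition", "labelBudget"))],
      list(labelBudget = budget,
           acquisition = do.call(acquisitionConfig, y$loop$acquisition)))),
    outputDir = y$outputDir,
    trainRatio = y$trainRatio)
}

#' Run a full experiment from a configuration
#'
#' Generates the synthetic corpus, screens it, splits it, runs the
#' active-learning loop, and (optionally) writes the run directory:
#' history JSONL, metrics CSV and a config snapshot.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @param writeArtifacts write outputs under \code{config$outputDir}.
#' @return the \linkS4class{ActiveRun}.
#' @export
runExperiment <- function(config, writeArtifacts = FALSE) {
  stopifnot(inherits(config, "experimentConfig"))
  ds <- generateDataset(config$synthetic)
  ds <- screenInvalid(ds)$valid
  ds <- stratifiedSplit(ds, trainRatio = config$trainRatio,
                        seed = deriveSeed(config$synthetic$seed, 5L))
  splits <- ds@manifest$split
  run <- runActiveLearning(config$loop, ds[splits == "train"],
                           ds[splits == "test"])
  if (writeArtifacts) {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    writeHistoryJsonl(runHistory(run),
                      file.path(config$outputDir, "history.jsonl"))
    utils::write.csv(runHistory(run),
                     file.path(config$outputDir, "metrics.csv"),
                     row.names = FALSE)
    writeExperimentConfig(config,
                          file.path(config$outputDir, "config.yaml"))
  }
  run
}
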