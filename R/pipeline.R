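#' Default pipeline configuration
#'
#' Encodes the study-protocol defaults: 30 m thinning cells, |r| < 0.8
#' screening, 10 replicate 80/20 subsample fits, 5397 background points,
#' r = 100 environmental-space grid, and the 85% / eigenvalue-1 stopping
#' rule of the variable-elimination loop.
#'
#' @param seed master seed; expanded into per-stage seeds by [stageSeeds()].
#' @param ... overrides for individual entries.
#' @return named list of settings.
#' @export
pipelineConfig <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    thinCellSize = 30,
    corThreshold = 0.8,
    nReplicates = 10,
    trainFrac = 0.8,
    nBackground = 5397,
    betaMultiplier = 1,
    nHingeKnots = 8,
    envGridRes = 100,
    cumThreshold = 85,
    eigThreshold = 1,
    minVars = 3,
    correctedOccupancy = TRUE,
    nRows = 150, nCols = 150,
    nOccA = 346, nOccB = 47
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  cfg
}

#' Run the full habitat-and-niche pipeline
#'
#' End-to-end analysis on supplied data or (by default) the bundled
#' synthetic scene: occurrence thinning, correlation screening, replicated
#' maximum-entropy habitat models for two species, habitat binarization and
#' overlap accounting, SRSS-ranked PCA variable elimination, and
#' kernel-smoothed niche overlap (Schoener's D) in PC1-PC2 space.
#'
#' @param config list from [pipelineConfig()].
#' @param scene optional list with `env`, `occA`, `occB`, `background` (as
#'   from [defaultScene()]); generated from the config seed when NULL.
#' @param outdir optional directory; when given, stage artifacts (maps,
#'   occurrence CSVs, JSON reports, elimination log TSV) are written there.
#' @param quiet suppress stage messages.
#' @return list of class "PipelineResult" with entries `thinned`,
#'   `screening`, `sdmA`, `sdmB`, `habitat` (binary maps + "OverlapReport"),
#'   `importance`, `elimination`, `niche` (grids, breadths, D, per-variable
#'   overlaps), `config`.
#' @export
runPipeline <- function(config = pipelineConfig(), scene = NULL,
                        outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) logMsg(...)
  seeds <- stageSeeds(config$seed)

  if (is.null(scene)) {
    say("stage synth: generating synthetic scene (seed %d)", config$seed)
    scene <- defaultScene(seed = config$seed, nRows = config$nRows,
                          nCols = config$nCols, nA = config$nOccA,
                          nB = config$nOccB,
                          nBackground = config$nBackground)
  }
  env <- scene$env

  # -- thinning ---------------------------------------------------------
  thinA <- thinOccurrences(scene$occA, env, config$thinCellSize, quiet = quiet)
  thinB <- thinOccurrences(scene$occB, env, config$thinCellSize, quiet = quiet)
  say("stage prep: thinned %s %d -> %d, %s %d -> %d",
      speciesName(thinA), nPoints(scene$occA), nPoints(thinA),
      speciesName(thinB), nPoints(scene$occB), nPoints(thinB))

  # -- correlation screening -------------------------------------------
  corRep <- pearsonMatrix(env)
  screening <- screenVariables(corRep, threshold = config$corThreshold)
  say("stage screen: retained %d of %d layers (|r| < %g)",
      length(screening$retained), nLayers(env), config$corThreshold)
  subStack <- envStack(lapply(screening$retained, function(nm) getLayer(env, nm)))

  # -- habitat models ---------------------------------------------------
  say("stage sdm: fitting %s", speciesName(thinA))
  sdmA <- replicateProtocol(thinA, scene$background, subStack,
                            nRep = config$nReplicates,
                            trainFrac = config$trainFrac,
                            seed = seeds["replicatesA"],
                            nHingeKnots = config$nHingeKnots,
                            betaMultiplier = config$betaMultiplier)
  say("stage sdm: fitting %s", speciesName(thinB))
  sdmB <- replicateProtocol(thinB, scene$background, subStack,
                            nRep = config$nReplicates,
                            trainFrac = config$trainFrac,
                            seed = seeds["replicatesB"],
                            nHingeKnots = config$nHingeKnots,
                            betaMultiplier = config$betaMultiplier)
  say("stage sdm: mean test AUC %s %.3f, %s %.3f",
      speciesName(thinA), sdmA$eval$meanTestAUC,
      speciesName(thinB), sdmB$eval$meanTestAUC)

  # -- habitat overlap --------------------------------------------------
  binA <- binarizeHabitat(sdmA$meanMap, sdmA$eval$sssThreshold)
  binB <- binarizeHabitat(sdmB$meanMap, sdmB$eval$sssThreshold)
  overlap <- overlapStats(binA, binB)
  say("stage habitat: areas %.2f / %.2f km2, overlap %.2f km2",
      overlap$area_A, overlap$area_B, overlap$area_intersection)

  # -- niche in environmental space ------------------------------------
  importance <- srssRank(sdmA$eval$contribution, sdmB$eval$contribution)
  bgValues <- sdmA$bgValues
  elim <- eliminateAndSelect(bgValues, importance,
                             cumThreshold = config$cumThreshold,
                             eigThreshold = config$eigThreshold,
                             minVars = config$minVars)
  say("stage niche: %d variables selected after %d elimination round(s)",
      length(elim$selected), nrow(elim$log))
  pca <- elim$pca
  bgScores <- pca$scores
  scoresA <- projectScores(pca, sdmA$presValues[, elim$selected, drop = FALSE])
  scoresB <- projectScores(pca, sdmB$presValues[, elim$selected, drop = FALSE])
  gridA <- buildEnvSpace(bgScores, scoresA, r = config$envGridRes,
                         corrected = config$correctedOccupancy,
                         species = speciesName(thinA))
  gridB <- buildEnvSpace(bgScores, scoresB, r = config$envGridRes,
                         corrected = config$correctedOccupancy,
                         species = speciesName(thinB))
  D <- schoenersD(gridA, gridB)
  say("stage niche: Schoener's D = %.3f", D)
  varOverlap <- lapply(stats::setNames(elim$selected, elim$selected),
                       function(v)
    variableOverlap1d(sdmA$presValues[, v], sdmB$presValues[, v],
                      bgValues[, v]))

  result <- structure(list(
    thinned = list(A = thinA, B = thinB),
    screening = screening,
    sdmA = sdmA, sdmB = sdmB,
    habitat = list(binA = binA, binB = binB, overlap = overlap),
    importance = importance,
    elimination = elim,
    niche = list(gridA = gridA, gridB = gridB, D = D,
                 breadthA = nicheBreadth(gridA), breadthB = nicheBreadth(gridB),
                 variableOverlap = varOverlap,
                 dim12 = pca$varianceFraction[1:2]),
    config = config
  ), class = "PipelineResult")

  if (!is.null(outdir)) writePipelineOutputs(result, scene, outdir)
  result
}

# write stage artifacts under outdir
writePipelineOutputs <- function(result, scene, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeOccurrences(list(result$thinned$A, result$thinned$B),
                   file.path(outdir, "occurrences_thinned.csv"))
  writeAsciiGrid(result$sdmA$meanMap, file.path(outdir, "suitability_A.asc"))
  writeAsciiGrid(result$sdmB$meanMap, file.path(outdir, "suitability_B.asc"))
  writeAsciiGrid(combinedHabitatMap(result$habitat$binA, result$habitat$binB),
                 file.path(outdir, "habitat_classes.asc"))
  utils::write.table(result$elimination$log,
                     file.path(outdir, "elimination_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  report <- list(
    thinned = list(A = nPoints(result$thinned$A), B = nPoints(result$thinned$B)),
    retained_layers = result$screening$retained,
    eval_A = result$sdmA$eval[c("meanTrainAUC", "meanTestAUC", "maxTSS",
                                "tssThreshold", "sssThreshold")],
    eval_B = result$sdmB$eval[c("meanTrainAUC", "meanTestAUC", "maxTSS",
                                "tssThreshold", "sssThreshold")],
    overlap = result$habitat$overlap[setdiff(names(result$habitat$overlap),
                                             "rounded")],
    selected_variables = result$elimination$selected,
    dim12_variance_percent = result$niche$dim12,
    schoeners_D = result$niche$D,
    niche_breadth = list(A = result$niche$breadthA, B = result$niche$breadthB),
    seed = result$config$seed
  )
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
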