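.allMeasures <- c("P", "M_ang", "M_abs", "d_a", "Mov_pct",
                  "b0pos", "b1pos", "b0posvel", "b1posvel")

.crockerSpec <- function(measure) {
  switch(measure,
         b0pos = list(mode = "pos", k = 0L),
         b1pos = list(mode = "pos", k = 1L),
         b0posvel = list(mode = "posvel", k = 0L),
         b1posvel = list(mode = "posvel", k = 1L),
         NULL)
}

#' Run the full model-selection study on one reference trajectory
#'
#' The end-to-end analysis: take (or generate) a reference trajectory,
#' simulate `nRuns` realizations of the interactive and of the control model
#' from the reference's initial configuration, summarize every trajectory by
#' the requested measures (order-parameter time series and/or crocker
#' matrices), compute per-run Euclidean / Frobenius distances to the
#' reference, and decide model preference per measure with
#' Bonferroni-corrected confidence intervals.
#'
#' When `reference` is `NULL` a pseudo-experiment is generated from the
#' interactive model (known ground truth: the interactive model should win),
#' using `nAgents`, `pattern`, `nFrames` and `dropoutRate`.
#'
#' @param reference A [TrajectorySet-class], or `NULL` to generate one.
#' @param measures Subset of `P`, `M_ang`, `M_abs`, `d_a`, `Mov_pct`,
#'   `b0pos`, `b1pos`, `b0posvel`, `b1posvel`.
#' @param nRuns Runs per model ensemble.
#' @param nAgents,pattern,nFrames,dropoutRate Pseudo-experiment settings
#'   (ignored when `reference` is supplied, except `nFrames` which then
#'   defaults to the reference's length).
#' @param intParams,conParams Model parameter sets for the two ensembles.
#' @param seed Integer seed for the whole study, or `NULL`.
#' @param nComparisons,alpha Passed to [compareModels()].
#' @param timeStride,nEps Crocker settings.
#' @return List with `table` (the [resultsTable()] data frame),
#'   `comparisons` (named list of [ComparisonResult-class]), and
#'   `reference` (the reference trajectory used).
#' @examples
#' \donttest{
#' res <- runModelSelection(nAgents = 10, nFrames = 120, nRuns = 5,
#'                          measures = c("d_a", "Mov_pct"), seed = 1)
#' res$table
#' }
#' @export
runModelSelection <- function(reference = NULL, measures = .allMeasures,
                              nRuns = 20L, nAgents = 25L,
                              pattern = "clustered", nFrames = 500L,
                              dropoutRate = 0,
                              intParams = aphidModelParams("interactive"),
                              conParams = aphidModelParams("control"),
                              seed = NULL, nComparisons = 81L, alpha = 0.05,
                              timeStride = 4L, nEps = 50L) {
  measures <- match.arg(measures, .allMeasures, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(reference)) {
    ic <- generateInitialConditions(nAgents, pattern)
    reference <- generatePseudoExperiment(ic, intParams, nFrames,
                                          dropoutRate = dropoutRate)
  } else {
    nFrames <- nFrames(reference)
  }
  ic <- initialConfiguration(reference)

  intRuns <- simulateEnsemble(ic, intParams, nFrames, nRuns)
  conRuns <- simulateEnsemble(ic, conParams, nFrames, nRuns)

  opMeasures <- intersect(measures, c("P", "M_ang", "M_abs", "d_a",
                                      "Mov_pct"))
  summaries <- list()
  if (length(opMeasures)) {
    summaries$op <- list(ref = computeOrderParameters(reference),
                         int = lapply(intRuns, computeOrderParameters),
                         con = lapply(conRuns, computeOrderParameters))
  }
  for (m in measures) {
    cs <- .crockerSpec(m)
    if (!is.null(cs)) {
      cc <- function(tr) computeCrocker(tr, cs$mode, cs$k, nEps = nEps,
                                        timeStride = timeStride)
      summaries[[m]] <- list(ref = cc(reference),
                             int = lapply(intRuns, cc),
                             con = lapply(conRuns, cc))
    }
  }

  comparisons <- list()
  for (m in measures) {
    if (m %in% opMeasures) {
      ref <- summaries$op$ref[[m]]
      dInt <- vapply(summaries$op$int, function(s)
        seriesDistance(ref, s[[m]]), numeric(1))
      dCon <- vapply(summaries$op$con, function(s)
        seriesDistance(ref, s[[m]]), numeric(1))
    } else {
      dInt <- vapply(summaries[[m]]$int, function(s)
        crockerDistance(summaries[[m]]$ref, s), numeric(1))
      dCon <- vapply(summaries[[m]]$con, function(s)
        crockerDistance(summaries[[m]]$ref, s), numeric(1))
    }
    comparisons[[m]] <- compareModels(dInt, dCon, measure = m,
                                      nComparisons = nComparisons,
                                      alpha = alpha)
  }
  list(table = resultsTable(comparisons), comparisons = comparisons,
       reference = reference)
}
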