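#' Run the full pipeline: simulate, extract, evaluate
#'
#' Chains the synthetic cohort generator, feature extraction and
#' per-participant leave-one-screen-out evaluation, writing every
#' artifact under `outDir`: the cohort CSVs under `data/`, the pooled
#' sequence and beat confusion tables, per-screen predictions, a cohort
#' summary JSON and a provenance record (configuration + seed + package
#' version) sufficient to regenerate everything.
#'
#' @param outDir output directory.
#' @param featureTag one of the eight tags in [featureTags()].
#' @param classifier a [classifierConfig()].
#' @param sim a [simulationConfig()].
#' @param M delta window half-width.
#' @param tolerant tolerant frame-window handling, see
#'   [beatFormantFeatures()].
#' @param force overwrite an existing data directory.
#' @param quiet suppress per-participant progress messages.
#' @return A list with the cohort `sequenceSummary` and `beatSummary`
#'   (`CohortSummary`), the pooled `sequenceConfusion`/`beatConfusion`
#'   tables and the per-participant results.
#' @export
runPipeline <- function(outDir, featureTag = "gamma+c_da",
                        classifier = classifierConfig(),
                        sim = simulationConfig(),
                        M = 2L, tolerant = FALSE, force = FALSE,
                        quiet = FALSE) {
  if (!featureTag %in% names(.featureTagDims))
    stop(sprintf("unknown feature tag '%s'; valid tags: %s", featureTag,
                 paste(names(.featureTagDims), collapse = ", ")), call. = FALSE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  dataDir <- file.path(outDir, "data")
  manifest <- simulateCohort(sim, dataDir, force = force)
  res <- evaluateCohort(manifest, featureTag, classifier, M = M,
                        tolerant = tolerant, quiet = quiet)
  writeConfusion(res$sequenceConfusion, file.path(outDir, "sequence_confusion.csv"))
  writeConfusion(res$beatConfusion, file.path(outDir, "beat_confusion.csv"))
  utils::write.csv(res$screenPredictions,
                   file.path(outDir, "screen_predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(featureTag = featureTag,
         featureDim = unname(.featureTagDims[featureTag]),
         sequence = list(meanMcr = res$sequenceSummary$meanMcr,
                         seMcr = res$sequenceSummary$seMcr,
                         pooledMcr = res$sequenceSummary$pooledMcr),
         beat = list(meanMcr = res$beatSummary$meanMcr,
                     seMcr = res$beatSummary$seMcr,
                     pooledMcr = res$beatSummary$pooledMcr)),
    file.path(outDir, "cohort_summary.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(package = "cardiovoice",
         version = as.character(utils::packageVersion("cardiovoice")),
         featureTag = featureTag, deltaWindow = M,
         classifier = unclass(classifier), simulation = unclass(sim)),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  if (!quiet)
    message(sprintf("feature set '%s' (%d-dim): pooled sequence MCR %.2f%%, beat MCR %.2f%%",
                    featureTag, .featureTagDims[[featureTag]],
                    res$sequenceSummary$pooledMcr, res$beatSummary$pooledMcr))
  invisible(res)
}

#' Leave-one-screen-out evaluation over a whole cohort
#'
#' Runs [losoEvaluate()] for every participant in the manifest and
#' aggregates the per-participant sequence and beat confusion tables
#' into cohort summaries.
#'
#' @param manifest a [CohortManifest-class].
#' @param featureTag feature-set tag.
#' @param classifier a [classifierConfig()].
#' @param M delta window half-width.
#' @param tolerant tolerant frame-window handling.
#' @param requireStrict enforce the 21-screen design per participant.
#' @param quiet suppress progress messages.
#' @return A list with `sequenceSummary`, `beatSummary`,
#'   `sequenceConfusion`, `beatConfusion`, `screenPredictions` and
#'   `perParticipant`.
#' @export
evaluateCohort <- function(manifest, featureTag = "gamma+c_da",
                           classifier = classifierConfig(), M = 2L,
                           tolerant = FALSE, requireStrict = TRUE,
                           quiet = FALSE) {
  ids <- unique(manifestTable(manifest)$participant_id)
  per <- vector("list", length(ids))
  names(per) <- ids
  for (p in ids) {
    screens <- participantScreenFeatures(manifest, p, featureTag,
                                         M = M, tolerant = tolerant)
    per[[p]] <- losoEvaluate(screens, classifier,
                             requireStrict = requireStrict)
    if (!quiet)
      message(sprintf("participant %s: sequence MCR %.2f%%", p,
                      overallMcr(per[[p]]$sequenceConfusion)))
  }
  preds <- do.call(rbind, lapply(ids, function(p)
    cbind(participant_id = p, per[[p]]$screenPredictions)))
  list(sequenceSummary = cohortSummary(lapply(per, `[[`, "sequenceConfusion")),
       beatSummary = cohortSummary(lapply(per, `[[`, "beatConfusion")),
       sequenceConfusion = ConfusionTable(Reduce(`+`, lapply(per, function(r)
         counts(r$sequenceConfusion)))),
       beatConfusion = ConfusionTable(Reduce(`+`, lapply(per, function(r)
         counts(r$beatConfusion)))),
       screenPredictions = preds,
       perParticipant = per)
}
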