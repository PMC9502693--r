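#' Build a confusion table from paired decisions
#'
#' @param actual,predicted integer vectors of levels in 1..3.
#' @return A [ConfusionTable-class].
#' @export
confusionTable <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted),
            all(actual %in% 1:3), all(predicted %in% 1:3))
  ct <- table(factor(actual, levels = 1:3), factor(predicted, levels = 1:3))
  ConfusionTable(matrix(as.integer(ct), 3, 3))
}

#' Misclassification and mistrust rates
#'
#' For a 3 x 3 confusion table with rows the actual level and columns
#' the classified level: the per-class misclassification rate is the
#' off-diagonal share of each row (how often that workload level was
#' missed), the per-class mistrust rate is the off-diagonal share of
#' each column (how often a classification into that level was wrong),
#' and the overall rate is the off-diagonal share of the grand total.
#' All are percentages computed at full precision; round only for
#' display. An empty row/column yields `NA` for that entry with a
#' warning rather than a silent zero.
#'
#' @param t a [ConfusionTable-class].
#' @return `mcrPerClass()`/`mtrPerClass()`: numeric 3-vectors (percent);
#'   `overallMcr()`: a single percentage.
#' @export
#' @examples
#' t3 <- ConfusionTable(rbind(c(569, 65, 45), c(51, 454, 77), c(23, 48, 705)))
#' round(mcrPerClass(t3), 2)  # 16.20 21.99 9.15
#' round(overallMcr(t3), 2)   # 15.17
mcrPerClass <- function(t) {
  ct <- counts(t)
  tot <- rowSums(ct)
  out <- 100 * (tot - diag(ct)) / tot
  if (any(tot == 0)) {
    warning("empty actual-level row(s); MCR undefined there")
    out[tot == 0] <- NA_real_
  }
  names(out) <- .levelLabels
  out
}

#' @rdname mcrPerClass
#' @export
mtrPerClass <- function(t) {
  ct <- counts(t)
  tot <- colSums(ct)
  out <- 100 * (tot - diag(ct)) / tot
  if (any(tot == 0)) {
    warning("empty classified-level column(s); MTR undefined there")
    out[tot == 0] <- NA_real_
  }
  names(out) <- .levelLabels
  out
}

#' @rdname mcrPerClass
#' @export
overallMcr <- function(t) {
  ct <- counts(t)
  tot <- sum(ct)
  if (tot <= 0) stop("confusion table is empty", call. = FALSE)
  100 * (tot - sum(diag(ct))) / tot
}

#' Leave-one-screen-out evaluation for one participant
#'
#' For each of the participant's screens, a model is trained on all the
#' other screens' beats and used to classify the held-out screen: one
#' sequence decision per screen (column-summed soft scores) and one
#' decision per heartbeat. Results accumulate into a sequence confusion
#' table (one entry per screen) and a beat confusion table. Each fold is
#' trained with seed `bitwXor(config$seed, fold)` so folds are
#' independent yet the whole evaluation is reproducible.
#'
#' @param screens list of labelled [BeatFeatureMatrix-class] objects, one
#'   per screen (all with the same tag; each screen's beats share its
#'   level).
#' @param config a [classifierConfig()].
#' @param requireStrict enforce the 21-screen 7/6/8 design (default);
#'   set `FALSE` to allow any screen set with >= 2 screens per level.
#' @return A list with `screenPredictions` (data.frame: screen, actual,
#'   predicted), `beatPredictions` (data.frame: screen, actual,
#'   predicted per beat), `sequenceConfusion` and `beatConfusion`
#'   ([ConfusionTable-class]).
#' @export
losoEvaluate <- function(screens, config = classifierConfig(),
                         requireStrict = TRUE) {
  stopifnot(is.list(screens), length(screens) >= 3L)
  tags <- vapply(screens, featureTag, character(1))
  if (length(unique(tags)) != 1L)
    stop("all screens must use the same feature set", call. = FALSE)
  lv <- vapply(screens, function(s) {
    l <- unique(beatLevels(s))
    if (length(l) != 1L) stop("each screen must have a single level label",
                              call. = FALSE)
    l
  }, integer(1))
  cnt <- tabulate(lv, 3)
  if (requireStrict) {
    if (length(screens) != 21L || !all(cnt == c(7L, 6L, 8L)))
      stop(sprintf("strict mode expects 21 screens with 7/6/8 per level, got %d (%s); set requireStrict = FALSE for other designs",
                   length(screens), paste(cnt, collapse = "/")), call. = FALSE)
  } else if (any(cnt < 2L)) {
    stop("leave-one-screen-out needs at least 2 screens of every level",
         call. = FALSE)
  }
  j <- length(screens)
  seqPred <- integer(j)
  beatRows <- vector("list", j)
  for (fold in seq_len(j)) {
    trainIdx <- setdiff(seq_len(j), fold)
    xs <- do.call(rbind, lapply(screens[trainIdx], featureMatrix))
    ls <- unlist(lapply(screens[trainIdx], beatLevels))
    trainFeats <- BeatFeatureMatrix(xs, tags[1],
                                    seq_len(nrow(xs)), levels = ls)
    cfg <- config
    cfg$seed <- bitwXor(config$seed, fold)
    model <- trainWorkloadModel(trainFeats, cfg)
    sc <- scoreBeats(model, screens[[fold]])
    seqPred[fold] <- classifySequence(sc)$level
    beatRows[[fold]] <- data.frame(screen = fold, actual = lv[fold],
                                   predicted = .classifyBeats(sc))
  }
  beatPred <- do.call(rbind, beatRows)
  list(screenPredictions = data.frame(screen = seq_len(j), actual = lv,
                                      predicted = seqPred),
       beatPredictions = beatPred,
       sequenceConfusion = confusionTable(lv, seqPred),
       beatConfusion = confusionTable(beatPred$actual, beatPred$predicted))
}

#' Build one participant's per-screen feature matrices from a manifest
#'
#' Reads the participant's beat and formant files, extracts the
#' requested feature set and labels every beat with the screen's level.
#'
#' @param manifest a [CohortManifest-class].
#' @param participant participant id present in the manifest.
#' @param tag feature-set tag, see [featureTags()].
#' @param M delta window half-width for the dynamic sets.
#' @param tolerant passed to [beatFormantFeatures()].
#' @return A list of labelled [BeatFeatureMatrix-class], one per screen
#'   in screen-index order.
#' @export
participantScreenFeatures <- function(manifest, participant, tag,
                                      M = 2L, tolerant = FALSE) {
  s <- manifestTable(manifest)
  s <- s[s$participant_id == participant, , drop = FALSE]
  if (!nrow(s)) stop(sprintf("participant '%s' not in manifest", participant),
                     call. = FALSE)
  s <- s[order(s$screen_index), , drop = FALSE]
  needF <- grepl("phi|gamma", tag)
  needC <- grepl("c", tag)
  lapply(seq_len(nrow(s)), function(i) {
    beats <- readBeatSeries(s$beat_file[i], participant, s$screen_index[i])
    ff <- NULL
    cf <- NULL
    if (needF) {
      track <- readFormantTrack(s$formant_file[i], participant, s$screen_index[i])
      ff <- beatFormantFeatures(track, beats,
                                withDynamics = grepl("gamma", tag),
                                M = M, tolerant = tolerant)
    }
    if (needC)
      cf <- cardioBeatFeatures(beats, withDynamics = grepl("c_da", tag), M = M)
    feats <- fuseFeatures(ff, cf)
    beatLevels(feats) <- rep(s$level[i], nrow(featureMatrix(feats)))
    feats
  })
}

#' Aggregate per-participant confusion tables
#'
#' Computes the per-participant overall misclassification rates, their
#' mean and standard error of the mean (sample sd / sqrt(P)), and the
#' pooled rate from the element-wise sum of the tables. Mean and pooled
#' rates can differ when participants contribute unequal counts; both
#' are reported.
#'
#' @param tables list of [ConfusionTable-class], one per participant.
#' @return A list of class `CohortSummary` with `perParticipantMcr`,
#'   `meanMcr`, `seMcr` (`NA` with a single participant), `pooledMcr`
#'   and `pooledTable`.
#' @export
cohortSummary <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "ConfusionTable")))
  per <- vapply(tables, overallMcr, numeric(1))
  pooled <- ConfusionTable(Reduce(`+`, lapply(tables, counts)))
  se <- if (length(per) >= 2L) stats::sd(per) / sqrt(length(per)) else NA_real_
  if (length(per) < 2L)
    warning("standard error undefined with a single participant")
  structure(list(perParticipantMcr = per,
                 meanMcr = mean(per), seMcr = se,
                 pooledMcr = overallMcr(pooled),
                 pooledTable = pooled),
            class = "CohortSummary")
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat(sprintf("Cohort of %d participant(s)\n", length(x$perParticipantMcr)))
  cat(sprintf("  mean MCR:   %.2f%% +/- %.2f (SE)\n", x$meanMcr, x$seMcr))
  cat(sprintf("  pooled MCR: %.2f%%\n", x$pooledMcr))
  invisible(x)
}
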