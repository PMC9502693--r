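#' @import methods
NULL

## Canonical on-disk schemas. Beat files carry the ten per-heartbeat
## hemodynamic measures in this fixed order; ibi_s duplicates the pulse
## interval so the measure set stays complete even though beat times are
## the authoritative clock.
.beatMeasureNames <- c("hr_bpm", "sbp_mmhg", "dbp_mmhg", "map_mmhg", "ibi_s",
                       "sv_ml", "lvpe", "co_lmin", "tpr", "dpdt_max")
.formantNames <- c("f1_hz", "f2_hz", "f3_hz")
.levelLabels <- c("L1", "L2", "L3")
.frameStep <- 0.010
.frameStepTol <- 1e-6

## The eight feature-set tags and their per-beat dimensions.
.featureTagDims <- c("phi" = 30L, "gamma" = 90L, "c" = 10L, "c_da" = 30L,
                     "phi+c" = 40L, "phi+c_da" = 60L,
                     "gamma+c" = 100L, "gamma+c_da" = 120L)

#' Feature-set tags
#'
#' The eight per-beat feature sets: formant statistics without (`phi`,
#' 30-dim) or with (`gamma`, 90-dim) frame-level delta/acceleration
#' expansion; cardiovascular measures without (`c`, 10-dim) or with
#' (`c_da`, 30-dim) dynamics; and the four fusions obtained by
#' concatenating a formant set with a cardiovascular set.
#'
#' @return Named integer vector mapping tag to feature dimension.
#' @export
#' @examples
#' featureTags()
featureTags <- function() .featureTagDims

#' BeatSeries: per-heartbeat cardiovascular measures
#'
#' One screen's beat-by-beat record: strictly increasing beat times (s)
#' and an N x 10 matrix of hemodynamic measures in the fixed column order
#' heart rate (bpm), systolic/diastolic/mean pressure (mmHg), pulse
#' interval (s), stroke volume (ml), left ventricular pressure energy,
#' cardiac output (l/min), total peripheral resistance, and maximum
#' steepness.
#'
#' @slot participantId character scalar.
#' @slot screenIndex integer screen index within the session.
#' @slot beatTimes numeric vector of beat times in seconds.
#' @slot measures numeric N x 10 matrix, columns as above.
#' @export
setClass("BeatSeries",
         slots = c(participantId = "character",
                   screenIndex = "integer",
                   beatTimes = "numeric",
                   measures = "matrix"))

setValidity("BeatSeries", function(object) {
  n <- length(object@beatTimes)
  if (n < 2L) return("a BeatSeries needs at least 2 beats")
  if (!all(is.finite(object@beatTimes)))
    return("beat times must be finite")
  if (any(diff(object@beatTimes) <= 0))
    return(sprintf("beat times must be strictly increasing (first violation at row %d)",
                   which(diff(object@beatTimes) <= 0)[1] + 1L))
  m <- object@measures
  if (!is.numeric(m) || nrow(m) != n || ncol(m) != 10L)
    return("measures must be a numeric N x 10 matrix matching beatTimes")
  if (!all(is.finite(m))) return("measures must be finite")
  if (!identical(colnames(m), .beatMeasureNames))
    return("measure columns must be named in the canonical order")
  if (any(m[, "ibi_s"] <= 0))
    return(sprintf("pulse-interval column must be positive (first violation at row %d)",
                   which(m[, "ibi_s"] <= 0)[1]))
  TRUE
})

#' Construct a BeatSeries
#'
#' @param participantId character id.
#' @param screenIndex integer screen index (1-based).
#' @param beatTimes numeric, strictly increasing beat times in seconds.
#' @param measures N x 10 numeric matrix; columns are taken to be in the
#'   canonical order and are renamed accordingly.
#' @return A [BeatSeries-class] object.
#' @export
#' @examples
#' m <- matrix(rep(c(86, 120, 70, 87, 0.7, 70, 1500, 6, 1, 1200), each = 3), 3)
#' BeatSeries("p1", 1L, c(1, 1.7, 2.4), m)
BeatSeries <- function(participantId, screenIndex, beatTimes, measures) {
  measures <- as.matrix(measures)
  colnames(measures) <- .beatMeasureNames
  new("BeatSeries", participantId = as.character(participantId),
      screenIndex = as.integer(screenIndex),
      beatTimes = as.numeric(beatTimes), measures = measures)
}

#' FormantTrack: frame-indexed formant frequencies
#'
#' One screen's formant track: frame start times on a uniform 10 ms grid
#' and an L x 3 matrix of the first three formant frequencies in Hz. The
#' ordering F1 <= F2 <= F3 is not enforced; tracker output is taken
#' as-is.
#'
#' @slot participantId character scalar.
#' @slot screenIndex integer screen index.
#' @slot frameTimes numeric frame times (s), uniform 10 ms spacing.
#' @slot formants numeric L x 3 matrix (f1_hz, f2_hz, f3_hz).
#' @export
setClass("FormantTrack",
         slots = c(participantId = "character",
                   screenIndex = "integer",
                   frameTimes = "numeric",
                   formants = "matrix"))

setValidity("FormantTrack", function(object) {
  l <- length(object@frameTimes)
  if (l < 3L) return("a FormantTrack needs at least 3 frames")
  d <- diff(object@frameTimes)
  dev <- max(abs(d - .frameStep))
  if (dev > .frameStepTol)
    return(sprintf("frame spacing must be uniform at 10 ms (max deviation %.3g s)", dev))
  f <- object@formants
  if (!is.numeric(f) || nrow(f) != l || ncol(f) != 3L)
    return("formants must be a numeric L x 3 matrix matching frameTimes")
  if (!all(is.finite(f)) || any(f <= 0))
    return("formant values must be positive and finite")
  if (!identical(colnames(f), .formantNames))
    return("formant columns must be f1_hz, f2_hz, f3_hz")
  TRUE
})

#' Construct a FormantTrack
#'
#' @param participantId character id.
#' @param screenIndex integer screen index.
#' @param frameTimes numeric frame times (s), uniformly spaced at 10 ms.
#' @param formants L x 3 numeric matrix of F1-F3 in Hz.
#' @return A [FormantTrack-class] object.
#' @export
FormantTrack <- function(participantId, screenIndex, frameTimes, formants) {
  formants <- as.matrix(formants)
  colnames(formants) <- .formantNames
  new("FormantTrack", participantId = as.character(participantId),
      screenIndex = as.integer(screenIndex),
      frameTimes = as.numeric(frameTimes), formants = formants)
}

#' CohortManifest: screen-level index of a cohort
#'
#' Rows of (participant_id, screen_index, level, beat_file, formant_file)
#' linking every Stroop screen to its two signal files. In strict mode a
#' participant must contribute exactly 21 screens: 7 at level 1, 6 at
#' level 2 and 8 at level 3.
#'
#' @slot screens data.frame with the five canonical columns.
#' @export
setClass("CohortManifest", slots = c(screens = "data.frame"))

setValidity("CohortManifest", function(object) {
  need <- c("participant_id", "screen_index", "level", "beat_file", "formant_file")
  if (!all(need %in% names(object@screens)))
    return(paste("manifest must have columns:", paste(need, collapse = ", ")))
  if (!all(object@screens$level %in% 1:3))
    return("levels must be in 1..3")
  TRUE
})

#' BeatFeatureMatrix: per-heartbeat feature rows
#'
#' An N x d matrix of per-beat features, one row per heartbeat, carrying
#' the feature-set tag (which fixes d, see [featureTags()]), the beat
#' times used for alignment checks, and (optionally) the per-beat
#' workload level labels.
#'
#' @slot features numeric N x d matrix.
#' @slot tag one of the eight feature-set tags.
#' @slot levels integer vector of per-beat levels (length N) or length 0.
#' @slot beatTimes numeric beat times (s), length N.
#' @export
setClass("BeatFeatureMatrix",
         slots = c(features = "matrix", tag = "character",
                   levels = "integer", beatTimes = "numeric"))

setValidity("BeatFeatureMatrix", function(object) {
  if (!object@tag %in% names(.featureTagDims))
    return(paste("unknown feature tag; valid tags:",
                 paste(names(.featureTagDims), collapse = ", ")))
  d <- .featureTagDims[[object@tag]]
  if (ncol(object@features) != d)
    return(sprintf("tag '%s' requires %d columns, got %d",
                   object@tag, d, ncol(object@features)))
  n <- nrow(object@features)
  if (length(object@beatTimes) != n)
    return("beatTimes length must equal the number of feature rows")
  if (length(object@levels) != 0L && length(object@levels) != n)
    return("levels must be empty or one per beat")
  if (length(object@levels) && !all(object@levels %in% 1:3))
    return("levels must be in 1..3")
  TRUE
})

BeatFeatureMatrix <- function(features, tag, beatTimes,
                              levels = integer(0)) {
  new("BeatFeatureMatrix", features = as.matrix(features), tag = tag,
      levels = as.integer(levels), beatTimes = as.numeric(beatTimes))
}

#' SoftScoreMatrix: per-beat class scores
#'
#' N x 3 matrix of soft scores, one row per heartbeat and one column per
#' workload level. For `margin_ovr` the entries are signed distances from
#' the three one-vs-rest decision boundaries (unconstrained reals); for
#' `tree_ensemble` they are tree-vote proportions in \[0,1\] summing to 1
#' per row.
#'
#' @slot scores numeric N x 3 matrix.
#' @slot kind "margin_ovr" or "tree_ensemble".
#' @export
setClass("SoftScoreMatrix",
         slots = c(scores = "matrix", kind = "character"))

setValidity("SoftScoreMatrix", function(object) {
  s <- object@scores
  if (ncol(s) != 3L) return("scores must have 3 columns")
  if (!all(is.finite(s))) return("scores must be finite")
  if (!object@kind %in% c("margin_ovr", "tree_ensemble"))
    return("kind must be margin_ovr or tree_ensemble")
  if (object@kind == "tree_ensemble") {
    if (any(s < -1e-9) || any(s > 1 + 1e-9))
      return("tree_ensemble scores must lie in [0, 1]")
    if (any(abs(rowSums(s) - 1) > 1e-8))
      return("tree_ensemble score rows must sum to 1")
  }
  TRUE
})

SoftScoreMatrix <- function(scores, kind) {
  scores <- as.matrix(scores)
  colnames(scores) <- .levelLabels
  new("SoftScoreMatrix", scores = scores, kind = kind)
}

#' ConfusionTable: actual vs classified counts
#'
#' A 3 x 3 table of counts with rows the actual Stroop level and columns
#' the classified level. Misclassification and mistrust rates derive from
#' it via [mcrPerClass()], [mtrPerClass()] and [overallMcr()].
#'
#' @slot counts integer 3 x 3 matrix.
#' @export
setClass("ConfusionTable", slots = c(counts = "matrix"))

setValidity("ConfusionTable", function(object) {
  ct <- object@counts
  if (!all(dim(ct) == c(3L, 3L))) return("counts must be 3 x 3")
  if (!all(is.finite(ct)) || any(ct < 0)) return("counts must be non-negative")
  if (any(abs(ct - round(ct)) > 1e-9)) return("counts must be integers")
  TRUE
})

#' Construct a ConfusionTable
#'
#' @param counts 3 x 3 numeric matrix of non-negative integer counts,
#'   rows = actual level, columns = classified level.
#' @return A [ConfusionTable-class] object.
#' @export
#' @examples
#' ConfusionTable(diag(c(7, 6, 8)))
ConfusionTable <- function(counts) {
  counts <- as.matrix(counts)
  dimnames(counts) <- list(actual = .levelLabels, classified = .levelLabels)
  new("ConfusionTable", counts = counts)
}

#' WorkloadModel: a trained per-participant classifier
#'
#' Bundles the fitted one-vs-rest margin classifiers (or tree ensemble),
#' the training-fold standardization parameters, the feature tag/dimension
#' and the configuration with its seed, so that scoring is reproducible.
#'
#' @slot kind "margin_ovr" or "tree_ensemble".
#' @slot fits list of fitted models (3 binary fits, or 1 ensemble).
#' @slot center,scale numeric standardization vectors (length d).
#' @slot tag feature tag the model was trained on.
#' @slot config the [classifierConfig()] list used.
#' @export
setClass("WorkloadModel",
         slots = c(kind = "character", fits = "list",
                   center = "numeric", scale = "numeric",
                   tag = "character", config = "list"))
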