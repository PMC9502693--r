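#' Accessors for cardiovoice objects
#'
#' Small accessor generics for the signal and feature containers:
#' `participantId()`, `screenIndex()`, `beatTimes()`, `measures()`,
#' `frameTimes()`, `formants()`, `featureMatrix()`, `featureTag()`,
#' `beatLevels()` (with a replacement form), `scoreMatrix()`, `counts()`
#' and `manifestTable()`.
#'
#' @param object a cardiovoice object.
#' @param value replacement value.
#' @return The slot contents; replacement forms return the modified
#'   object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("screenIndex", function(object) standardGeneric("screenIndex"))
#' @rdname accessors
#' @export
setGeneric("beatTimes", function(object) standardGeneric("beatTimes"))
#' @rdname accessors
#' @export
setGeneric("measures", function(object) standardGeneric("measures"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("formants", function(object) standardGeneric("formants"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("featureTag", function(object) standardGeneric("featureTag"))
#' @rdname accessors
#' @export
setGeneric("beatLevels", function(object) standardGeneric("beatLevels"))
#' @rdname accessors
#' @export
setGeneric("beatLevels<-", function(object, value) standardGeneric("beatLevels<-"))
#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(object) standardGeneric("scoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
#' @rdname accessors
#' @export
setGeneric("manifestTable", function(object) standardGeneric("manifestTable"))

#' @rdname accessors
setMethod("participantId", "BeatSeries", function(object) object@participantId)
#' @rdname accessors
setMethod("participantId", "FormantTrack", function(object) object@participantId)
#' @rdname accessors
setMethod("screenIndex", "BeatSeries", function(object) object@screenIndex)
#' @rdname accessors
setMethod("screenIndex", "FormantTrack", function(object) object@screenIndex)
#' @rdname accessors
setMethod("beatTimes", "BeatSeries", function(object) object@beatTimes)
#' @rdname accessors
setMethod("beatTimes", "BeatFeatureMatrix", function(object) object@beatTimes)
#' @rdname accessors
setMethod("measures", "BeatSeries", function(object) object@measures)
#' @rdname accessors
setMethod("frameTimes", "FormantTrack", function(object) object@frameTimes)
#' @rdname accessors
setMethod("formants", "FormantTrack", function(object) object@formants)
#' @rdname accessors
setMethod("featureMatrix", "BeatFeatureMatrix", function(object) object@features)
#' @rdname accessors
setMethod("featureTag", "BeatFeatureMatrix", function(object) object@tag)
#' @rdname accessors
setMethod("beatLevels", "BeatFeatureMatrix", function(object) object@levels)
#' @rdname accessors
setMethod("beatLevels<-", "BeatFeatureMatrix", function(object, value) {
  object@levels <- as.integer(value)
  validObject(object)
  object
})
#' @rdname accessors
setMethod("scoreMatrix", "SoftScoreMatrix", function(object) object@scores)
#' @rdname accessors
setMethod("counts", "ConfusionTable", function(object) object@counts)
#' @rdname accessors
setMethod("manifestTable", "CohortManifest", function(object) object@screens)

setMethod("show", "BeatSeries", function(object) {
  cat(sprintf("BeatSeries: participant %s, screen %d, %d beats over %.1f s\n",
              object@participantId, object@screenIndex,
              length(object@beatTimes),
              diff(range(object@beatTimes))))
})

setMethod("show", "FormantTrack", function(object) {
  cat(sprintf("FormantTrack: participant %s, screen %d, %d frames (10 ms) over %.2f s\n",
              object@participantId, object@screenIndex,
              length(object@frameTimes),
              diff(range(object@frameTimes))))
})

setMethod("show", "CohortManifest", function(object) {
  s <- object@screens
  cat(sprintf("CohortManifest: %d participants, %d screens (levels %s)\n",
              length(unique(s$participant_id)), nrow(s),
              paste(tabulate(s$level, 3), collapse = "/")))
})

setMethod("show", "BeatFeatureMatrix", function(object) {
  cat(sprintf("BeatFeatureMatrix '%s': %d beats x %d features%s\n",
              object@tag, nrow(object@features), ncol(object@features),
              if (length(object@levels)) ", labelled" else ""))
})

setMethod("show", "SoftScoreMatrix", function(object) {
  cat(sprintf("SoftScoreMatrix (%s): %d beats x 3 levels\n",
              object@kind, nrow(object@scores)))
})

setMethod("show", "ConfusionTable", function(object) {
  print(object@counts)
  cat(sprintf("overall MCR: %.2f%%\n", overallMcr(object)))
})

setMethod("show", "WorkloadModel", function(object) {
  cat(sprintf("WorkloadModel (%s) on '%s' features (%d-dim)\n",
              object@kind, object@tag, length(object@center)))
})
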