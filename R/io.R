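## One CSV dialect everywhere: comma-separated, decimal point, UTF-8,
## mandatory header. Explicit schemas beat positional guessing.

.checkHeader <- function(got, want, what, path) {
  missing <- setdiff(want, got)
  extra <- setdiff(got, want)
  if (length(missing))
    stop(sprintf("%s '%s': missing column(s) %s", what, path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (length(extra))
    stop(sprintf("%s '%s': unexpected column(s) %s", what, path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  if (!identical(got, want))
    stop(sprintf("%s '%s': columns must be in canonical order %s", what, path,
                 paste(want, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

.checkFinite <- function(df, cols, what, path) {
  for (cl in cols) {
    bad <- !is.finite(df[[cl]])
    if (any(bad))
      stop(sprintf("%s '%s': non-finite value in column %s (row %d)",
                   what, path, cl, which(bad)[1]), call. = FALSE)
  }
  invisible(TRUE)
}

.readCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read and write beat-by-beat cardiovascular files
#'
#' A beat file has one data row per heartbeat and the canonical header
#' `time_s, hr_bpm, sbp_mmhg, dbp_mmhg, map_mmhg, ibi_s, sv_ml, lvpe,
#' co_lmin, tpr, dpdt_max`. The `time_s` column is the authoritative beat
#' clock; `ibi_s` is carried as a feature. Files are rejected with the
#' offending column/row named if the header deviates, values are
#' non-finite, beat times are not strictly increasing or pulse intervals
#' are not positive.
#'
#' @param path file path.
#' @param participantId,screenIndex identifiers attached to the object
#'   (the file itself carries only signal columns).
#' @return `readBeatSeries()` returns a [BeatSeries-class];
#'   `writeBeatSeries()` invisibly returns `path`.
#' @export
readBeatSeries <- function(path, participantId = "unknown", screenIndex = 1L) {
  df <- .readCsv(path)
  want <- c("time_s", .beatMeasureNames)
  .checkHeader(names(df), want, "beat file", path)
  .checkFinite(df, want, "beat file", path)
  if (nrow(df) < 2L)
    stop(sprintf("beat file '%s': need at least 2 beats, got %d", path, nrow(df)),
         call. = FALSE)
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad))
    stop(sprintf("beat file '%s': beat times not strictly increasing at row %d",
                 path, bad[1] + 1L), call. = FALSE)
  bad <- which(df$ibi_s <= 0)
  if (length(bad))
    stop(sprintf("beat file '%s': non-positive pulse interval at row %d",
                 path, bad[1]), call. = FALSE)
  BeatSeries(participantId, screenIndex, df$time_s,
             as.matrix(df[, .beatMeasureNames]))
}

#' @rdname readBeatSeries
#' @param beats a [BeatSeries-class] object.
#' @export
writeBeatSeries <- function(beats, path) {
  stopifnot(is(beats, "BeatSeries"))
  df <- data.frame(time_s = beats@beatTimes, beats@measures,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write formant-track files
#'
#' A formant file has one row per 10 ms analysis frame with header
#' `time_s, f1_hz, f2_hz, f3_hz`. Frame spacing must be uniform at 10 ms
#' (tolerance 1e-6 s; violations are reported with the maximum
#' deviation), formant values must be positive and finite, and at least 3
#' frames are required.
#'
#' @param path file path.
#' @param participantId,screenIndex identifiers attached to the object.
#' @return `readFormantTrack()` returns a [FormantTrack-class];
#'   `writeFormantTrack()` invisibly returns `path`.
#' @export
readFormantTrack <- function(path, participantId = "unknown", screenIndex = 1L) {
  df <- .readCsv(path)
  want <- c("time_s", .formantNames)
  .checkHeader(names(df), want, "formant file", path)
  .checkFinite(df, want, "formant file", path)
  if (nrow(df) < 3L)
    stop(sprintf("formant file '%s': need at least 3 frames, got %d",
                 path, nrow(df)), call. = FALSE)
  dev <- max(abs(diff(df$time_s) - .frameStep))
  if (dev > .frameStepTol)
    stop(sprintf("formant file '%s': non-uniform frame spacing (max deviation %.3g s from 10 ms)",
                 path, dev), call. = FALSE)
  for (cl in .formantNames) {
    bad <- which(df[[cl]] <= 0)
    if (length(bad))
      stop(sprintf("formant file '%s': non-positive %s at row %d",
                   path, cl, bad[1]), call. = FALSE)
  }
  FormantTrack(participantId, screenIndex, df$time_s,
               as.matrix(df[, .formantNames]))
}

#' @rdname readFormantTrack
#' @param track a [FormantTrack-class] object.
#' @export
writeFormantTrack <- function(track, path) {
  stopifnot(is(track, "FormantTrack"))
  df <- data.frame(time_s = track@frameTimes, track@formants,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate per-participant screen counts of a manifest
#'
#' Strict mode enforces the session design: exactly 21 screens per
#' participant, 7 at level 1, 6 at level 2, 8 at level 3. Lenient mode
#' only requires at least 2 screens of every level (the minimum for
#' leave-one-screen-out training to see all classes).
#'
#' @param manifest a [CohortManifest-class].
#' @param strict logical.
#' @return The manifest, invisibly; errors list the offending
#'   participants.
#' @export
validateManifest <- function(manifest, strict = TRUE) {
  s <- manifestTable(manifest)
  bad <- character(0)
  for (p in unique(s$participant_id)) {
    lv <- s$level[s$participant_id == p]
    cnt <- tabulate(lv, 3)
    ok <- if (strict) length(lv) == 21L && all(cnt == c(7L, 6L, 8L))
          else all(cnt >= 2L)
    if (!ok) bad <- c(bad, sprintf("%s (%s screens, levels %s)",
                                   p, length(lv), paste(cnt, collapse = "/")))
  }
  if (length(bad))
    stop(sprintf("%s manifest check failed for participant(s): %s",
                 if (strict) "strict (21 screens, 7/6/8)" else "lenient (>=2 per level)",
                 paste(bad, collapse = "; ")), call. = FALSE)
  invisible(manifest)
}

#' Read and write cohort manifests
#'
#' A manifest CSV has columns `participant_id, screen_index, level,
#' beat_file, formant_file`; relative file paths are resolved against the
#' manifest's directory on read.
#'
#' @param path file path.
#' @param strict enforce the 21-screen 7/6/8 design per participant
#'   (default); lenient mode only requires >= 2 screens per level.
#' @return `readManifest()` returns a [CohortManifest-class];
#'   `writeManifest()` invisibly returns `path`.
#' @export
readManifest <- function(path, strict = TRUE) {
  df <- .readCsv(path)
  want <- c("participant_id", "screen_index", "level", "beat_file", "formant_file")
  .checkHeader(names(df), want, "manifest", path)
  df$participant_id <- as.character(df$participant_id)
  df$screen_index <- as.integer(df$screen_index)
  df$level <- as.integer(df$level)
  base <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", df$beat_file)
  df$beat_file[rel] <- file.path(base, df$beat_file[rel])
  rel <- !grepl("^(/|[A-Za-z]:)", df$formant_file)
  df$formant_file[rel] <- file.path(base, df$formant_file[rel])
  m <- new("CohortManifest", screens = df)
  validateManifest(m, strict = strict)
  m
}

#' @rdname readManifest
#' @param manifest a [CohortManifest-class].
#' @export
writeManifest <- function(manifest, path) {
  stopifnot(is(manifest, "CohortManifest"))
  utils::write.csv(manifestTable(manifest), path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write 3 x 3 confusion tables
#'
#' Confusion CSVs carry a leading `actual` label column and columns
#' `L1, L2, L3`; rows are the actual level, columns the classified level.
#'
#' @param path file path.
#' @return `readConfusion()` returns a [ConfusionTable-class];
#'   `writeConfusion()` invisibly returns `path`.
#' @export
readConfusion <- function(path) {
  df <- .readCsv(path)
  .checkHeader(names(df), c("actual", .levelLabels), "confusion file", path)
  if (nrow(df) != 3L || !identical(as.character(df$actual), .levelLabels))
    stop(sprintf("confusion file '%s': rows must be labelled L1, L2, L3", path),
         call. = FALSE)
  ConfusionTable(as.matrix(df[, .levelLabels]))
}

#' @rdname readConfusion
#' @param table a [ConfusionTable-class].
#' @export
writeConfusion <- function(table, path) {
  stopifnot(is(table, "ConfusionTable"))
  df <- data.frame(actual = .levelLabels, counts(table), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and write per-beat feature matrices
#'
#' Feature CSVs have columns `beat_time_s`, `level` (0 when unlabelled)
#' and one named column per feature; the feature-set tag is stored in the
#' column names and re-derived on read.
#'
#' @param path file path.
#' @param tag feature-set tag expected in the file.
#' @return `readFeatureMatrix()` returns a [BeatFeatureMatrix-class];
#'   `writeFeatureMatrix()` invisibly returns `path`.
#' @export
readFeatureMatrix <- function(path, tag) {
  df <- .readCsv(path)
  want <- c("beat_time_s", "level", featureNamesForTag(tag))
  .checkHeader(names(df), want, "feature file", path)
  lv <- as.integer(df$level)
  BeatFeatureMatrix(as.matrix(df[, featureNamesForTag(tag), drop = FALSE]),
                    tag, df$beat_time_s,
                    levels = if (all(lv == 0L)) integer(0) else lv)
}

#' @rdname readFeatureMatrix
#' @param feats a [BeatFeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(feats, path) {
  stopifnot(is(feats, "BeatFeatureMatrix"))
  lv <- beatLevels(feats)
  x <- featureMatrix(feats)
  colnames(x) <- featureNamesForTag(featureTag(feats))
  df <- data.frame(beat_time_s = beatTimes(feats),
                   level = if (length(lv)) lv else 0L,
                   x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
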