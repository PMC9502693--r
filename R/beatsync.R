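.statNames <- c("poly_a", "poly_b", "poly_c", "min", "max", "mean",
                "median", "sd", "skew", "kurt")

.trackNamesFor <- function(withDynamics) {
  base <- c("F1", "F2", "F3")
  if (withDynamics) c(base, paste0("d", base), paste0("a", base)) else base
}

#' Canonical feature column names for a feature-set tag
#'
#' @param tag one of the eight tags in [featureTags()].
#' @return Character vector of length `featureTags()[tag]`.
#' @export
featureNamesForTag <- function(tag) {
  if (!tag %in% names(.featureTagDims))
    stop(sprintf("unknown feature tag '%s'; valid tags: %s", tag,
                 paste(names(.featureTagDims), collapse = ", ")), call. = FALSE)
  formant <- function(dyn) as.vector(t(outer(.trackNamesFor(dyn), .statNames,
                                             paste, sep = "_")))
  cardio <- function(dyn) {
    if (dyn) c(.beatMeasureNames, paste0("d_", .beatMeasureNames),
               paste0("a_", .beatMeasureNames))
    else .beatMeasureNames
  }
  switch(tag,
         "phi" = formant(FALSE),
         "gamma" = formant(TRUE),
         "c" = cardio(FALSE),
         "c_da" = cardio(TRUE),
         "phi+c" = c(formant(FALSE), cardio(FALSE)),
         "phi+c_da" = c(formant(FALSE), cardio(TRUE)),
         "gamma+c" = c(formant(TRUE), cardio(FALSE)),
         "gamma+c_da" = c(formant(TRUE), cardio(TRUE)))
}

#' Assign formant frames to heartbeats
#'
#' Partitions the track's time axis into one half-open window per
#' heartbeat, `(tau_n - Delta_n/2, tau_n + Delta_{n+1}/2]`, where
#' `Delta_n = tau_n - tau_{n-1}` is the pulse interval. The first beat's
#' left half-width reuses `Delta_2` and the last beat's right half-width
#' reuses `Delta_N`, so consecutive windows tile the covered span with no
#' gaps and no frame owned twice; frames outside the span are dropped.
#' The right-closed convention gives every edge frame exactly one owner
#' (the earlier window).
#'
#' @param beats a [BeatSeries-class].
#' @param track a [FormantTrack-class] overlapping the beat span.
#' @param tolerant if `FALSE` (default) any window with fewer than 3
#'   frames is an error listing the beat indices; if `TRUE` such windows
#'   are flagged for downstream copy-previous handling.
#' @return A list with `left`, `right` (numeric window edges, length N),
#'   `frames` (list of frame-index vectors per beat) and `short`
#'   (indices of windows with < 3 frames; non-empty only when
#'   `tolerant = TRUE`).
#' @export
assignFrames <- function(beats, track, tolerant = FALSE) {
  stopifnot(is(beats, "BeatSeries"), is(track, "FormantTrack"))
  tau <- beatTimes(beats)
  n <- length(tau)
  delta <- diff(tau)                       # delta[i] = Delta_{i+1} = tau_{i+1}-tau_i
  leftHalf <- c(delta[1], delta)           # Delta_n for beat n, Delta_1 := Delta_2
  rightHalf <- c(delta, delta[n - 1L])     # Delta_{n+1} for beat n, Delta_{N+1} := Delta_N
  left <- tau - leftHalf / 2
  right <- tau + rightHalf / 2
  t <- frameTimes(track)
  if (max(t) <= left[1] || min(t) > right[n])
    stop("formant track does not overlap the beat span", call. = FALSE)
  breaks <- c(left[1], right)
  owner <- findInterval(t, breaks, left.open = TRUE)
  owner[owner < 1L | owner > n] <- NA_integer_
  frames <- split(seq_along(t)[!is.na(owner)], owner[!is.na(owner)])
  framesFull <- rep(list(integer(0)), n)
  framesFull[as.integer(names(frames))] <- frames
  nFrames <- lengths(framesFull)
  short <- which(nFrames < 3L)
  if (length(short) && !tolerant)
    stop(sprintf("window(s) with fewer than 3 frames at beat(s) %s; use tolerant mode to copy the previous beat's features",
                 paste(short, collapse = ", ")), call. = FALSE)
  list(left = left, right = right, frames = framesFull, short = short)
}

#' Per-window track statistics
#'
#' The ten summary statistics of one formant (or delta/acceleration)
#' track within one heartbeat window: the three coefficients of a
#' least-squares quadratic fitted on frame times re-centred at the beat
#' time (descending degree, so `poly_c` is the fitted at-beat level),
#' then minimum, maximum, mean, median, standard deviation (n-1),
#' skewness (biased moment estimator) and plain kurtosis (non-excess; 3
#' for a normal). A zero-variance window returns skewness 0 and kurtosis
#' 3 by convention rather than NaN, with zero curvature and slope.
#'
#' @param values numeric track values of the frames in one window
#'   (length >= 3).
#' @param times frame times (s) of those frames.
#' @param tau beat time (s) used to centre the polynomial fit.
#' @return Named numeric vector of the 10 statistics.
#' @export
trackStats <- function(values, times, tau) {
  k <- length(values)
  if (k < 3L || length(times) != k)
    stop("a window needs at least 3 frames and matching times", call. = FALSE)
  mn <- mean(values)
  if (max(values) == min(values)) {
    out <- c(0, 0, values[1], values[1], values[1], values[1], values[1], 0, 0, 3)
    names(out) <- .statNames
    return(out)
  }
  tc <- times - tau
  fit <- stats::lm.fit(cbind(tc^2, tc, 1), values)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  s <- stats::sd(values)
  m2 <- mean((values - mn)^2)
  skew <- if (m2 > 0) mean((values - mn)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((values - mn)^4) / m2^2 else 3
  out <- c(cf[1], cf[2], cf[3], min(values), max(values), mn,
           stats::median(values), s, skew, kurt)
  names(out) <- .statNames
  out
}

#' Heartbeat-synchronised formant statistics
#'
#' Computes the per-beat formant feature matrix: the track is cut into
#' one window per heartbeat ([assignFrames()]) and each track is
#' summarised by the 10 statistics of [trackStats()]. Without dynamics
#' the 3 formant tracks give the N x 30 set (`phi`), ordered all 10
#' statistics of F1, then F2, then F3. With dynamics the frame-level
#' matrix is expanded to 9 tracks first ([expandDynamics()]) and then
#' summarised, giving the N x 90 set (`gamma`); dynamics are never
#' re-applied to the beat-level statistics.
#'
#' @param track a [FormantTrack-class].
#' @param beats a [BeatSeries-class].
#' @param withDynamics expand the frame matrix with delta/acceleration
#'   tracks before summarising.
#' @param M delta window half-width, see [deltaFeatures()].
#' @param tolerant copy the previous beat's feature row for windows with
#'   fewer than 3 frames instead of erroring.
#' @return A [BeatFeatureMatrix-class] with tag `"phi"` or `"gamma"`.
#' @export
beatFormantFeatures <- function(track, beats, withDynamics = FALSE,
                                M = 2L, tolerant = FALSE) {
  stopifnot(is(track, "FormantTrack"), is(beats, "BeatSeries"))
  win <- assignFrames(beats, track, tolerant = tolerant)
  f <- formants(track)
  if (withDynamics) f <- expandDynamics(f, M)
  t <- frameTimes(track)
  tau <- beatTimes(beats)
  n <- length(tau)
  d <- 10L * ncol(f)
  out <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    idx <- win$frames[[i]]
    if (length(idx) < 3L) {
      if (i == 1L)
        stop("first beat window has fewer than 3 frames; nothing to copy",
             call. = FALSE)
      out[i, ] <- out[i - 1L, ]
      next
    }
    out[i, ] <- as.vector(vapply(seq_len(ncol(f)), function(j)
      trackStats(f[idx, j], t[idx], tau[i]), numeric(10L)))
  }
  tag <- if (withDynamics) "gamma" else "phi"
  colnames(out) <- featureNamesForTag(tag)
  BeatFeatureMatrix(out, tag, tau)
}

#' Per-beat cardiovascular features
#'
#' The ten per-heartbeat measures as-is (`c`, N x 10) or with
#' delta/acceleration expansion along the beat index (`c_da`, N x 30).
#'
#' @param beats a [BeatSeries-class].
#' @param withDynamics append delta and acceleration features.
#' @param M delta window half-width.
#' @return A [BeatFeatureMatrix-class] with tag `"c"` or `"c_da"`.
#' @export
cardioBeatFeatures <- function(beats, withDynamics = FALSE, M = 2L) {
  stopifnot(is(beats, "BeatSeries"))
  x <- measures(beats)
  if (withDynamics) x <- expandDynamics(x, M)
  tag <- if (withDynamics) "c_da" else "c"
  colnames(x) <- featureNamesForTag(tag)
  BeatFeatureMatrix(x, tag, beatTimes(beats))
}

#' Feature-level fusion of formant and cardiovascular features
#'
#' Row-wise concatenation `[formant | cardio]` of two beat-aligned
#' feature matrices; the two inputs must describe the same heartbeats
#' (same count and same beat times). Passing a single source through
#' (with the other `NULL`) is allowed for the single-modality baselines.
#' The four fused tags have dimensions 40 (`phi+c`), 60 (`phi+c_da`),
#' 100 (`gamma+c`) and 120 (`gamma+c_da`).
#'
#' @param formantFeats [BeatFeatureMatrix-class] with tag `phi`/`gamma`,
#'   or `NULL`.
#' @param cardioFeats [BeatFeatureMatrix-class] with tag `c`/`c_da`, or
#'   `NULL`.
#' @return A [BeatFeatureMatrix-class] with the fused (or passthrough)
#'   tag.
#' @export
fuseFeatures <- function(formantFeats = NULL, cardioFeats = NULL) {
  if (is.null(formantFeats) && is.null(cardioFeats))
    stop("at least one feature source is required", call. = FALSE)
  if (is.null(cardioFeats)) return(formantFeats)
  if (is.null(formantFeats)) return(cardioFeats)
  stopifnot(is(formantFeats, "BeatFeatureMatrix"),
            is(cardioFeats, "BeatFeatureMatrix"))
  if (!featureTag(formantFeats) %in% c("phi", "gamma") ||
      !featureTag(cardioFeats) %in% c("c", "c_da"))
    stop("fusion takes a formant set (phi/gamma) and a cardiovascular set (c/c_da)",
         call. = FALSE)
  nf <- nrow(featureMatrix(formantFeats))
  nc <- nrow(featureMatrix(cardioFeats))
  if (nf != nc)
    stop(sprintf("beat-count mismatch: formant features have %d beats, cardiovascular %d",
                 nf, nc), call. = FALSE)
  if (max(abs(beatTimes(formantFeats) - beatTimes(cardioFeats))) > 1e-9)
    stop("beat alignment mismatch: the two feature sets describe different heartbeats",
         call. = FALSE)
  tag <- paste(featureTag(formantFeats), featureTag(cardioFeats), sep = "+")
  lvF <- beatLevels(formantFeats); lvC <- beatLevels(cardioFeats)
  if (length(lvF) && length(lvC) && !identical(lvF, lvC))
    stop("per-beat level labels disagree between the two sources", call. = FALSE)
  BeatFeatureMatrix(cbind(featureMatrix(formantFeats), featureMatrix(cardioFeats)),
                    tag, beatTimes(formantFeats),
                    levels = if (length(lvF)) lvF else lvC)
}
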