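## Stationary AR(1) noise with sd `s` (innovation sd scaled accordingly).
.ar1 <- function(n, phi, s) {
  if (s <= 0 || n == 0L) return(numeric(n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, s)
  if (n > 1L) {
    e <- stats::rnorm(n - 1L, 0, s * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1L] + e[i - 1L]
  }
  x
}

## Deterministic per-(participant, screen) seed below 2^31.
.mixSeed <- function(seed, p, j) {
  as.integer((abs(as.numeric(seed)) + p * 7919 + j * 104729) %% 2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Simulation configuration for a synthetic Stroop-style cohort
#'
#' Defines a cohort of participants each performing 21 screens (7 at
#' level 1, 6 at level 2, 8 at level 3). Beat sequences arise from
#' jittered pulse intervals around a participant baseline heart rate
#' (drawn from N(86, 8) bpm, i.e. roughly 0.7 s intervals) shifted
#' upward with workload level; the ten cardiovascular measures combine
#' participant baselines, additive level effects and AR(1) beat-to-beat
#' noise, with mean pressure, cardiac output and peripheral resistance
#' derived from their constituents.
#' Formant tracks at 100 frames/s are built from five vowel-template
#' segments (one per colour word) with a level-dependent shift of the
#' formant means and, at level 3, the paced 0.75/0.65 s word
#' presentation replacing self-paced segment durations.
#'
#' @param nParticipants number of participants.
#' @param screenDuration screen length in seconds (default 30).
#' @param baseHrMean,baseHrSd participant baseline heart-rate
#'   distribution (bpm).
#' @param hrLevelEffect additive bpm shift per level (monotone by
#'   default: workload raises heart rate).
#' @param pulseJitterSd extra white jitter on each pulse interval (s).
#' @param arCoef AR(1) coefficient of the beat-to-beat cardiovascular
#'   noise.
#' @param effectScale multiplier on every level effect (cardiovascular
#'   and formant); `0` gives the null cohort with identical per-level
#'   distributions.
#' @param pacedLevel3 use the paced 0.75/0.65 s segment durations at
#'   level 3 (part of the level-3 manipulation; switched off in the null
#'   cohort).
#' @param formantShift 3 x 3 matrix of additive Hz shifts (level x
#'   formant).
#' @param frameNoiseSd,frameArCoef within-segment formant noise (Hz) and
#'   its AR(1) coefficient.
#' @param segmentDurMean,segmentDurSd self-paced segment duration (s).
#' @param seed master seed; every screen derives its own seed from it.
#' @return A list of class `simulationConfig`.
#' @export
simulationConfig <- function(nParticipants = 10L,
                             screenDuration = 30,
                             baseHrMean = 86, baseHrSd = 8,
                             hrLevelEffect = c(0, 3.5, 7),
                             pulseJitterSd = 0.015,
                             arCoef = 0.8,
                             effectScale = 1,
                             pacedLevel3 = TRUE,
                             formantShift = rbind(c(0, 0, 0),
                                                  c(20, 30, 15),
                                                  c(40, 60, 30)),
                             frameNoiseSd = 15, frameArCoef = 0.95,
                             segmentDurMean = 0.55, segmentDurSd = 0.08,
                             seed = 1L) {
  stopifnot(nParticipants >= 1L, screenDuration > 0,
            pulseJitterSd >= 0, frameNoiseSd >= 0, segmentDurSd >= 0,
            abs(arCoef) < 1, abs(frameArCoef) < 1,
            all(is.finite(hrLevelEffect)), all(is.finite(formantShift)))
  structure(list(
    nParticipants = as.integer(nParticipants),
    screensPerLevel = c(7L, 6L, 8L),
    screenDuration = screenDuration,
    baseHrMean = baseHrMean, baseHrSd = baseHrSd,
    hrLevelEffect = hrLevelEffect,
    pulseJitterSd = pulseJitterSd, arCoef = arCoef,
    effectScale = effectScale, pacedLevel3 = pacedLevel3,
    ## participant baseline mean/sd for the directly generated measures
    cardioBase = list(sbp = c(120, 8), dbp = c(70, 6), sv = c(70, 8),
                      lvpe = c(1500, 150), dpdt = c(1200, 120)),
    ## additive level effects (L1/L2/L3) per measure
    cardioEffect = list(sbp = c(0, 4, 8), dbp = c(0, 2, 4),
                        sv = c(0, -1.5, -3), lvpe = c(0, 30, 60),
                        dpdt = c(0, 40, 80)),
    ## stationary AR(1) beat-noise sd per measure
    cardioNoiseSd = c(hr = 2.5, sbp = 3, dbp = 2, sv = 3,
                      lvpe = 60, dpdt = 50, map = 1, co = 0.15, tpr = 0.03),
    ## five vowel templates (F1, F2, F3 in Hz), one per colour word
    vowelTemplates = rbind(a = c(700, 1200, 2600),
                           e = c(500, 1900, 2600),
                           i = c(300, 2300, 3000),
                           o = c(450, 900, 2500),
                           u = c(350, 800, 2400)),
    participantFormantSd = 25,
    formantShift = formantShift,
    frameNoiseSd = frameNoiseSd, frameArCoef = frameArCoef,
    segmentDurMean = segmentDurMean, segmentDurSd = segmentDurSd,
    pacedDurations = c(0.75, 0.65),
    seed = as.integer(seed)),
    class = "simulationConfig")
}

#' Draw one participant's baseline parameters
#'
#' @param config a [simulationConfig()].
#' @param p participant index (used to derive the seed).
#' @return A list of baselines (heart rate, pressures, volumes, formant
#'   offsets).
#' @export
participantParams <- function(config, p) {
  .withSeed(.mixSeed(config$seed, p, 0L), {
    b <- config$cardioBase
    list(id = sprintf("p%03d", p),
         hrBase = stats::rnorm(1, config$baseHrMean, config$baseHrSd),
         sbpBase = stats::rnorm(1, b$sbp[1], b$sbp[2]),
         dbpBase = stats::rnorm(1, b$dbp[1], b$dbp[2]),
         svBase = stats::rnorm(1, b$sv[1], b$sv[2]),
         lvpeBase = stats::rnorm(1, b$lvpe[1], b$lvpe[2]),
         dpdtBase = stats::rnorm(1, b$dpdt[1], b$dpdt[2]),
         formantOffset = stats::rnorm(3, 0, config$participantFormantSd))
  })
}

#' Simulate one Stroop screen
#'
#' Generates the beat series and formant track for one screen at the
#' given workload level. Beat times accumulate jittered pulse intervals
#' around the level-shifted heart rate; the ten measures combine
#' baseline, level effect and AR(1) noise (mean pressure,
#' cardiac output and total peripheral resistance are derived from the
#' generated pressures, rate and stroke volume). The formant track
#' concatenates vowel-template segments with level-shifted targets and
#' AR(1) frame noise; at level 3 the paced 0.75/0.65 s presentation sets
#' the segment durations.
#'
#' @param participant a [participantParams()] list.
#' @param level workload level 1..3.
#' @param config a [simulationConfig()].
#' @param screenIndex screen index recorded in the objects.
#' @param seed RNG seed for this screen.
#' @param duration screen length (s); defaults to the config's.
#' @return A list with `beats` ([BeatSeries-class]) and `track`
#'   ([FormantTrack-class]).
#' @export
simulateScreen <- function(participant, level, config = simulationConfig(),
                           screenIndex = 1L, seed = 1L,
                           duration = config$screenDuration) {
  stopifnot(level %in% 1:3)
  es <- config$effectScale
  .withSeed(seed, {
    ## --- beats ---
    hrTarget <- participant$hrBase + es * config$hrLevelEffect[level]
    nMax <- ceiling(duration / (60 / (max(hrTarget, 40) + 30))) + 10L
    hrNoise <- .ar1(nMax, config$arCoef, config$cardioNoiseSd[["hr"]])
    hr <- pmax(hrTarget + hrNoise, 30)
    ibi <- pmax(60 / hr + stats::rnorm(nMax, 0, config$pulseJitterSd), 0.25)
    tau <- cumsum(ibi)
    keep <- tau <= duration
    n <- sum(keep)
    if (n < 2L)
      stop(sprintf("screen duration %.2f s too short for 2 heartbeats", duration),
           call. = FALSE)
    tau <- tau[keep]; ibi <- ibi[keep]

    eff <- lapply(config$cardioEffect, function(e) es * e[level])
    nsd <- config$cardioNoiseSd
    sbp <- participant$sbpBase + eff$sbp + .ar1(n, config$arCoef, nsd[["sbp"]])
    dbp <- participant$dbpBase + eff$dbp + .ar1(n, config$arCoef, nsd[["dbp"]])
    dbp <- pmin(dbp, sbp - 5)
    map <- dbp + (sbp - dbp) / 3 + stats::rnorm(n, 0, nsd[["map"]])
    sv <- pmax(participant$svBase + eff$sv + .ar1(n, config$arCoef, nsd[["sv"]]), 20)
    hrBeat <- 60 / ibi
    co <- pmax(hrBeat * sv / 1000 + stats::rnorm(n, 0, nsd[["co"]]), 0.5)
    # TPR in medical units: MAP over flow in ml/s
    tpr <- pmax(map / (co * 1000 / 60) + stats::rnorm(n, 0, nsd[["tpr"]]), 0.05)
    lvpe <- pmax(participant$lvpeBase + eff$lvpe + .ar1(n, config$arCoef, nsd[["lvpe"]]), 100)
    dpdt <- pmax(participant$dpdtBase + eff$dpdt + .ar1(n, config$arCoef, nsd[["dpdt"]]), 100)
    m <- cbind(hrBeat, sbp, dbp, map, ibi, sv, lvpe, co, tpr, dpdt)
    beats <- BeatSeries(participant$id, screenIndex, tau, m)

    ## --- formant track ---
    L <- round(duration * 100)
    t <- seq_len(L) * .frameStep
    segDur <- numeric(0)
    while (sum(segDur) < duration) {
      d <- if (level == 3L && config$pacedLevel3)
        config$pacedDurations[(length(segDur) %% 2L) + 1L]
      else pmax(stats::rnorm(1, config$segmentDurMean, config$segmentDurSd), 0.2)
      segDur <- c(segDur, d)
    }
    segEnd <- cumsum(segDur)
    segIdx <- findInterval(t, c(0, segEnd), left.open = TRUE)
    segIdx <- pmin(segIdx, length(segDur))
    vowels <- sample.int(nrow(config$vowelTemplates), length(segDur), replace = TRUE)
    shift <- es * config$formantShift[level, ]
    fm <- vapply(1:3, function(jf) {
      target <- config$vowelTemplates[vowels[segIdx], jf] +
        participant$formantOffset[jf] + shift[jf]
      pmax(target + .ar1(L, config$frameArCoef, config$frameNoiseSd), 50)
    }, numeric(L))
    track <- FormantTrack(participant$id, screenIndex, t, fm)
    list(beats = beats, track = track)
  })
}

## The six level-block orders; participants cycle through them,
## emulating a Latin-square assignment.
.levelOrders <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L),
                     c(1L, 3L, 2L), c(2L, 1L, 3L), c(3L, 2L, 1L))

#' Cohort design table
#'
#' The screen-by-screen layout of a cohort (participant, screen index,
#' level and the file names [simulateCohort()] would write), without
#' generating any signals. Levels are presented in blocks whose order
#' rotates over six permutations across participants.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with columns participant_id, screen_index, level,
#'   beat_file, formant_file.
#' @export
cohortDesign <- function(config = simulationConfig()) {
  rows <- lapply(seq_len(config$nParticipants), function(p) {
    ord <- .levelOrders[[(p - 1L) %% 6L + 1L]]
    lev <- rep(ord, times = config$screensPerLevel[ord])
    pid <- sprintf("p%03d", p)
    data.frame(participant_id = pid,
               screen_index = seq_along(lev),
               level = lev,
               beat_file = sprintf("%s_s%02d_beats.csv", pid, seq_along(lev)),
               formant_file = sprintf("%s_s%02d_formants.csv", pid, seq_along(lev)))
  })
  do.call(rbind, rows)
}

#' Simulate a cohort to disk
#'
#' Writes every screen's beat and formant CSV plus a strict-mode-valid
#' `manifest.csv` into `dir`. Each screen's RNG seed derives
#' deterministically from the master seed, the participant index and the
#' screen index, so the same configuration reproduces byte-identical
#' files.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory.
#' @param force overwrite an existing non-empty directory.
#' @return The [CohortManifest-class], invisibly; the manifest path is
#'   attached as attribute `"path"`.
#' @export
simulateCohort <- function(config = simulationConfig(), dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !force)
    stop(sprintf("output directory '%s' exists and is not empty; use force = TRUE", dir),
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  design <- cohortDesign(config)
  for (p in seq_len(config$nParticipants)) {
    pid <- sprintf("p%03d", p)
    pars <- participantParams(config, p)
    rows <- design[design$participant_id == pid, ]
    for (i in seq_len(nrow(rows))) {
      j <- rows$screen_index[i]
      sim <- simulateScreen(pars, rows$level[i], config, screenIndex = j,
                            seed = .mixSeed(config$seed, p, j))
      writeBeatSeries(sim$beats, file.path(dir, rows$beat_file[i]))
      writeFormantTrack(sim$track, file.path(dir, rows$formant_file[i]))
    }
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  m <- readManifest(path, strict = TRUE)
  attr(m, "path") <- path
  invisible(m)
}
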