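# Independent brute-force oracles: literal formula evaluation, written
# without reference to the package internals they check.

# Delta regression coefficients, literal double loop with edge clamping.
oracleDelta <- function(x, M = 2L) {
  x <- as.matrix(x)
  R <- nrow(x)
  out <- matrix(0, R, ncol(x))
  denom <- 2 * sum((1:M)^2)
  for (r in seq_len(R)) {
    for (i in seq_len(ncol(x))) {
      s <- 0
      for (m in seq_len(M)) {
        fwd <- min(r + m, R)
        bwd <- max(r - m, 1L)
        s <- s + m * (x[fwd, i] - x[bwd, i])
      }
      out[r, i] <- s / denom
    }
  }
  out
}

# The ten window statistics by naive formulas: quadratic fit through
# explicit normal equations, direct moment sums.
oracleStats <- function(values, times, tau) {
  k <- length(values)
  if (max(values) == min(values))
    return(c(0, 0, values[1], values[1], values[1], values[1], values[1], 0, 0, 3))
  tc <- times - tau
  X <- cbind(tc^2, tc, rep(1, k))
  cf <- solve(t(X) %*% X, t(X) %*% values)
  mu <- sum(values) / k
  m2 <- sum((values - mu)^2) / k
  m3 <- sum((values - mu)^3) / k
  m4 <- sum((values - mu)^4) / k
  sorted <- sort(values)
  med <- if (k %% 2 == 1) sorted[(k + 1) / 2] else (sorted[k / 2] + sorted[k / 2 + 1]) / 2
  c(cf[1], cf[2], cf[3], min(values), max(values), mu, med,
    sqrt(sum((values - mu)^2) / (k - 1)), m3 / m2^1.5, m4 / m2^2)
}

# Frame-to-beat ownership by exhaustive per-frame scan over all windows.
oracleOwners <- function(tau, t) {
  n <- length(tau)
  delta <- diff(tau)
  left <- tau - c(delta[1], delta) / 2
  right <- tau + c(delta, delta[n - 1]) / 2
  owner <- rep(NA_integer_, length(t))
  for (l in seq_along(t)) {
    for (w in seq_len(n)) {
      if (t[l] > left[w] && t[l] <= right[w]) {
        if (!is.na(owner[l])) stop("frame owned twice")
        owner[l] <- w
      }
    }
  }
  owner
}

# A valid 10-column measure matrix around resting physiology.
makeMeasures <- function(n, ibi = rep(0.7, n)) {
  m <- cbind(60 / ibi, 120, 70, 87, ibi, 70, 1500, 6, 1, 1200) +
    matrix(stats::rnorm(n * 10, 0, 0.01), n, 10)
  m[, 5] <- ibi
  m
}

makeBeats <- function(times, id = "t", screen = 1L) {
  n <- length(times)
  BeatSeries(id, screen, times, makeMeasures(n, ibi = c(diff(times)[1], diff(times))))
}

# Uniform 100 Hz track covering [step, duration].
makeTrack <- function(duration, f = NULL, id = "t", screen = 1L) {
  t <- seq_len(round(duration * 100)) * 0.01
  if (is.null(f))
    f <- cbind(500 + 20 * sin(t), 1500 + 30 * cos(t), 2500 + 10 * sin(2 * t))
  FormantTrack(id, screen, t, f)
}

# Labelled cardio-tag feature matrix with three Gaussian clusters on a
# simplex (class k offset along coordinate k, so each one-vs-rest split
# is linearly separable).
makeClusterFeatures <- function(nPerClass = 50, offset = 10, sd = 1, seed = 1) {
  set.seed(seed)
  n <- 3 * nPerClass
  lv <- rep(1:3, each = nPerClass)
  x <- matrix(stats::rnorm(n * 10, 0, sd), n, 10)
  x[cbind(seq_len(n), lv)] <- x[cbind(seq_len(n), lv)] + offset
  colnames(x) <- featureNamesForTag("c")
  f <- BeatFeatureMatrix(x, "c", seq_len(n) * 0.7)
  beatLevels(f) <- lv
  f
}

# Per-screen labelled cardio features straight from the generator.
makeParticipantScreens <- function(cfg, p = 1L, tag = "c") {
  design <- cohortDesign(cfg)
  pid <- sprintf("p%03d", p)
  rows <- design[design$participant_id == pid, ]
  pars <- participantParams(cfg, p)
  lapply(seq_len(nrow(rows)), function(i) {
    sim <- simulateScreen(pars, rows$level[i], cfg, screenIndex = i,
                          seed = cfg$seed * 1000L + p * 100L + i)
    fx <- cardioBeatFeatures(sim$beats, withDynamics = grepl("c_da", tag))
    beatLevels(fx) <- rep(rows$level[i], nrow(featureMatrix(fx)))
    fx
  })
}

tempCsv <- function() tempfile(fileext = ".csv")
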