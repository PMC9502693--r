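test_that("a 0.7 s pulse at 100 frames/s puts 70 frames in each interior window", {
  # beats offset from the frame grid so no window edge sits on a frame
  beats <- makeBeats(seq(0.7, 14, by = 0.7) + 0.005)
  track <- makeTrack(14)
  win <- assignFrames(beats, track)
  interior <- lengths(win$frames)[2:(length(win$frames) - 1L)]
  expect_true(all(interior == 70L))
})

test_that("windows are half-open (left, right]: an edge frame belongs to the earlier window", {
  # beats at exact binary fractions so the shared edge 1.25 is exact
  beats <- makeBeats(c(1.0, 1.5, 2.0))
  t <- (76:224) * 0.01
  track <- FormantTrack("t", 1L, t,
                        matrix(rep(c(500, 1500, 2500), each = length(t)), ncol = 3))
  win <- assignFrames(beats, track)
  expect_equal(win$right[1], 1.25)
  edge <- which(t == 1.25)
  expect_true(edge %in% win$frames[[1]])
  expect_false(edge %in% win$frames[[2]])
})

test_that("window edges and memberships match the exhaustive per-frame oracle", {
  beats <- makeBeats(c(1.0, 1.7, 2.4))
  track <- makeTrack(3)
  win <- assignFrames(beats, track)
  expect_equal(win$left[2], 1.35, tolerance = 1e-12)
  expect_equal(win$right[2], 2.05, tolerance = 1e-12)
  own <- oracleOwners(beatTimes(beats), frameTimes(track))
  expect_equal(length(win$frames[[2]]), sum(own == 2, na.rm = TRUE))
  for (w in 1:3)
    expect_equal(win$frames[[w]], which(!is.na(own) & own == w))
})

test_that("window tiling covers the beat span with every frame owned at most once", {
  set.seed(314)
  for (rep in 1:20) {
    n <- sample(4:15, 1)
    tau <- cumsum(runif(n, 0.4, 1.2))
    beats <- makeBeats(tau)
    track <- makeTrack(max(tau) + 1)
    win <- assignFrames(beats, track, tolerant = TRUE)
    delta <- diff(tau)
    expect_equal(sum(win$right - win$left),
                 (tau[n] + delta[n - 1] / 2) - (tau[1] - delta[1] / 2),
                 tolerance = 1e-12)
    expect_equal(win$right[-n], win$left[-1], tolerance = 1e-12)
    own <- oracleOwners(tau, frameTimes(track))
    expect_equal(unlist(win$frames), which(!is.na(own)))
    expect_equal(anyDuplicated(unlist(win$frames)), 0L)
  }
})

test_that("windows with fewer than 3 frames error by default and copy-forward in tolerant mode", {
  tau <- c(0.5, 1.2, 1.22, 1.24, 1.9)  # third window ~2 frames wide
  beats <- makeBeats(tau)
  track <- makeTrack(2.5)
  expect_error(assignFrames(beats, track), "fewer than 3 frames")
  ff <- beatFormantFeatures(track, beats, tolerant = TRUE)
  x <- featureMatrix(ff)
  expect_equal(x[3, ], x[2, ])  # copied row
  expect_false(isTRUE(all.equal(x[4, ], x[3, ])))
})

test_that("track statistics handle constants by convention and recover exact quadratics", {
  s <- trackStats(rep(500, 10), seq(0, 0.09, by = 0.01), 0.05)
  expect_equal(unname(s), c(0, 0, 500, 500, 500, 500, 500, 0, 0, 3))

  t <- seq(-0.3, 0.3, by = 0.01) + 5     # centred at tau = 5
  v <- 2 * (t - 5)^2 + 3 * (t - 5) + 400
  s <- trackStats(v, t, 5)
  expect_equal(unname(s[1:3]), c(2, 3, 400), tolerance = 1e-6)
})

test_that("all ten statistics agree with the naive-formula oracle on random windows", {
  set.seed(2718)
  for (rep in 1:300) {
    k <- sample(c(3:8, 60:80), 1)
    t <- sort(runif(1, 0, 10) + seq_len(k) * 0.01)
    v <- rnorm(k, 500, 50)
    tau <- runif(1, min(t), max(t))  # a beat lies inside its own window
    expect_equal(unname(trackStats(v, t, tau)), oracleStats(v, t, tau),
                 tolerance = 1e-9)
  }
})

test_that("beat formant features have the documented shapes with and without dynamics", {
  beats <- makeBeats(seq(0.7, 21, by = 0.7))  # 30 beats
  track <- makeTrack(21.5)
  phi <- beatFormantFeatures(track, beats, withDynamics = FALSE)
  gam <- beatFormantFeatures(track, beats, withDynamics = TRUE)
  expect_equal(dim(featureMatrix(phi)), c(30L, 30L))
  expect_equal(featureTag(phi), "phi")
  expect_equal(dim(featureMatrix(gam)), c(30L, 90L))
  expect_equal(featureTag(gam), "gamma")

  # constant tracks: the delta/acceleration-track statistics collapse to
  # the zero-variance convention (everything 0 except kurtosis 3)
  flat <- FormantTrack("t", 1L, frameTimes(track),
                       matrix(rep(c(500, 1500, 2500), each = length(frameTimes(track))),
                              ncol = 3))
  g0 <- featureMatrix(beatFormantFeatures(flat, beats, withDynamics = TRUE))
  dynCols <- featureNamesForTag("gamma")[31:90]
  kurt <- grepl("_kurt$", dynCols)
  expect_true(all(g0[, dynCols[kurt]] == 3))
  expect_true(all(g0[, dynCols[!kurt]] == 0))
})

test_that("fusion concatenates beat-aligned sources and rejects misaligned ones", {
  beats <- makeBeats(seq(0.7, 14, by = 0.7))
  track <- makeTrack(14.5)
  gam <- beatFormantFeatures(track, beats, withDynamics = TRUE)
  phi <- beatFormantFeatures(track, beats, withDynamics = FALSE)
  cda <- cardioBeatFeatures(beats, withDynamics = TRUE)
  c0 <- cardioBeatFeatures(beats, withDynamics = FALSE)

  fused <- fuseFeatures(gam, cda)
  expect_equal(featureTag(fused), "gamma+c_da")
  expect_equal(ncol(featureMatrix(fused)), 120L)
  expect_equal(featureMatrix(fused)[, 1:90], featureMatrix(gam))
  expect_equal(ncol(featureMatrix(fuseFeatures(phi, c0))), 40L)
  expect_equal(ncol(featureMatrix(fuseFeatures(phi, cda))), 60L)
  expect_equal(ncol(featureMatrix(fuseFeatures(gam, c0))), 100L)
  expect_equal(featureTag(fuseFeatures(gam, NULL)), "gamma")

  other <- makeBeats(seq(0.7, 10.5, by = 0.7))
  expect_error(fuseFeatures(gam, cardioBeatFeatures(other)), "15")
  shifted <- makeBeats(seq(0.7, 14, by = 0.7) + 0.1)
  expect_error(fuseFeatures(gam, cardioBeatFeatures(shifted)), "alignment")
})
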