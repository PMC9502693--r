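test_that("a 30 s screen at a steady 70 bpm contains exactly 35 heartbeats", {
  cfg <- simulationConfig(baseHrMean = 70, baseHrSd = 0, seed = 1)
  cfg$cardioNoiseSd["hr"] <- 0
  cfg$pulseJitterSd <- 0
  pars <- participantParams(cfg, 1)
  sim <- simulateScreen(pars, 1, cfg, seed = 99, duration = 30)
  expect_equal(length(beatTimes(sim$beats)), 35L)
  expect_equal(measures(sim$beats)[, "hr_bpm"], rep(70, 35), tolerance = 1e-9)
})

test_that("too short a screen for two heartbeats is an error", {
  cfg <- simulationConfig(seed = 1)
  pars <- participantParams(cfg, 1)
  expect_error(simulateScreen(pars, 1, cfg, seed = 5, duration = 0.5), "too short")
})

test_that("the same seed reproduces a screen exactly and cohort files byte-identically", {
  cfg <- simulationConfig(nParticipants = 1, seed = 33)
  pars <- participantParams(cfg, 1)
  s1 <- simulateScreen(pars, 2, cfg, seed = 77)
  s2 <- simulateScreen(pars, 2, cfg, seed = 77)
  expect_identical(beatTimes(s1$beats), beatTimes(s2$beats))
  expect_identical(measures(s1$beats), measures(s2$beats))
  expect_identical(formants(s1$track), formants(s2$track))

  d1 <- tempfile(); d2 <- tempfile()
  simulateCohort(cfg, d1)
  simulateCohort(cfg, d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_error(simulateCohort(cfg, d1), "force")
})

test_that("cohort designs have the 21-screen 7/6/8 structure at published cohort sizes", {
  d97 <- cohortDesign(simulationConfig(nParticipants = 97))
  expect_equal(nrow(d97), 2037L)
  expect_equal(unname(table(d97$level)), c(679L, 582L, 776L), ignore_attr = TRUE)

  d20 <- cohortDesign(simulationConfig(nParticipants = 20))
  expect_equal(nrow(d20), 420L)
  expect_equal(as.integer(table(d20$level)), c(140L, 120L, 160L))

  # level-block orders rotate across participants
  firstLevels <- vapply(split(d20$level, d20$participant_id), `[`, integer(1), 1)
  expect_gt(length(unique(firstLevels)), 1L)
})

test_that("generated cohorts re-read cleanly and feed the feature extractors", {
  cfg <- simulationConfig(nParticipants = 2, seed = 44)
  dir <- tempfile()
  m <- simulateCohort(cfg, dir)
  expect_s4_class(m, "CohortManifest")
  m2 <- readManifest(file.path(dir, "manifest.csv"), strict = TRUE)
  expect_equal(nrow(manifestTable(m2)), 42L)
  screens <- participantScreenFeatures(m2, "p001", "gamma+c")
  expect_length(screens, 21L)
  expect_true(all(vapply(screens, function(s) ncol(featureMatrix(s)) == 100L, logical(1))))
  expect_true(all(vapply(screens, function(s) length(unique(beatLevels(s))) == 1L, logical(1))))
})

test_that("with all level effects zeroed the per-level signal distributions coincide", {
  cfg <- simulationConfig(effectScale = 0, pacedLevel3 = FALSE, seed = 1)
  pars <- participantParams(cfg, 1)
  nSeeds <- 20
  rejectHr <- 0; rejectF1 <- 0
  for (s in seq_len(nSeeds)) {
    # screen-mean summaries are the exchangeable unit (beats within a
    # screen are AR(1)-correlated); 8 screens per level
    hr1 <- f1a <- hr3 <- f1b <- numeric(8)
    for (j in 1:8) {
      a <- simulateScreen(pars, 1, cfg, seed = 10000 + 100 * s + j)
      b <- simulateScreen(pars, 3, cfg, seed = 20000 + 100 * s + j)
      hr1[j] <- mean(measures(a$beats)[, "hr_bpm"])
      hr3[j] <- mean(measures(b$beats)[, "hr_bpm"])
      f1a[j] <- mean(formants(a$track)[, "f1_hz"])
      f1b[j] <- mean(formants(b$track)[, "f1_hz"])
    }
    if (t.test(hr1, hr3)$p.value < 0.01) rejectHr <- rejectHr + 1
    if (t.test(f1a, f1b)$p.value < 0.01) rejectF1 <- rejectF1 + 1
  }
  expect_lte(rejectHr, 2)
  expect_lte(rejectF1, 2)
})

test_that("level effects are monotone for heart rate by default", {
  cfg <- simulationConfig(seed = 9)
  expect_true(all(diff(cfg$hrLevelEffect) > 0))
  pars <- participantParams(cfg, 1)
  mns <- vapply(1:3, function(k) {
    mean(vapply(1:6, function(j)
      mean(measures(simulateScreen(pars, k, cfg, seed = 500 + 10 * k + j)$beats)[, "hr_bpm"]),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mns) > 0))
})
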