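t3counts <- rbind(c(569, 65, 45), c(51, 454, 77), c(23, 48, 705))
t4counts <- rbind(c(113, 12, 15), c(6, 96, 18), c(5, 17, 138))

test_that("per-class and overall rates follow the off-diagonal/total definitions", {
  t3 <- ConfusionTable(t3counts)
  expect_equal(round(unname(mcrPerClass(t3)), 2), c(16.20, 21.99, 9.15))
  expect_equal(round(unname(mtrPerClass(t3)), 2), c(11.51, 19.93, 14.75))
  expect_equal(round(overallMcr(t3), 2), 15.17)

  t4 <- ConfusionTable(t4counts)
  expect_equal(round(unname(mcrPerClass(t4)), 2), c(19.29, 20.00, 13.75))
  expect_equal(round(unname(mtrPerClass(t4)), 2), c(8.87, 23.20, 19.30))
  expect_equal(round(overallMcr(t4), 2), 17.38)

  diagOnly <- ConfusionTable(diag(c(7, 6, 8)))
  expect_equal(unname(mcrPerClass(diagOnly)), c(0, 0, 0))
  expect_equal(unname(mtrPerClass(diagOnly)), c(0, 0, 0))
  expect_equal(overallMcr(diagOnly), 0)
})

test_that("row and column decompositions both recover the off-diagonal total", {
  set.seed(5)
  for (rep in 1:10) {
    ct <- ConfusionTable(matrix(rpois(9, 40), 3, 3))
    m <- counts(ct)
    off <- sum(m) - sum(diag(m))
    expect_equal(sum(mcrPerClass(ct) * rowSums(m)), 100 * off, tolerance = 1e-9)
    expect_equal(sum(mtrPerClass(ct) * colSums(m)), 100 * off, tolerance = 1e-9)
  }
})

test_that("empty rows or columns are flagged as undefined, not reported as zero", {
  ct <- ConfusionTable(rbind(c(0, 0, 0), c(1, 5, 1), c(0, 2, 9)))
  expect_warning(m <- mcrPerClass(ct), "undefined")
  expect_true(is.na(m[1]))
  expect_false(anyNA(m[2:3]))
})

test_that("cohort aggregation reports mean/SE and the pooled ratio", {
  # two participants with overall MCRs 10% and 20%
  p1 <- ConfusionTable(rbind(c(9, 1, 0), c(0, 9, 1), c(0, 0, 0)))   # 2/20 = 10%
  p2 <- ConfusionTable(rbind(c(8, 2, 0), c(0, 8, 2), c(0, 0, 0)))   # 4/20 = 20%
  cs <- cohortSummary(list(p1, p2))
  expect_equal(cs$meanMcr, 15)
  expect_equal(cs$seMcr, 5)

  # identical tables: pooled equals mean
  cs2 <- cohortSummary(list(p1, p1, p1))
  expect_equal(cs2$pooledMcr, cs2$meanMcr)

  # random tables: pooled equals the metric of the element-wise sum
  set.seed(6)
  tabs <- lapply(1:5, function(i) ConfusionTable(matrix(rpois(9, 30), 3, 3)))
  cs3 <- cohortSummary(tabs)
  summed <- Reduce(`+`, lapply(tabs, counts))
  off <- sum(summed) - sum(diag(summed))
  expect_equal(cs3$pooledMcr, 100 * off / sum(summed), tolerance = 1e-12)

  expect_warning(cs1 <- cohortSummary(list(p1)), "single participant")
  expect_true(is.na(cs1$seMcr))
})

test_that("confusion files round-trip through the metrics entry point", {
  p <- tempfile(fileext = ".csv")
  writeConfusion(ConfusionTable(t3counts), p)
  expect_equal(round(overallMcr(readConfusion(p)), 2), 15.17)
})

test_that("leave-one-screen-out yields one sequence decision per screen", {
  cfg <- simulationConfig(nParticipants = 1, seed = 21)
  screens <- makeParticipantScreens(cfg, 1, tag = "c")
  res <- losoEvaluate(screens, classifierConfig("margin_ovr", seed = 2))
  expect_equal(sum(counts(res$sequenceConfusion)), 21)
  expect_equal(unname(rowSums(counts(res$sequenceConfusion))), c(7, 6, 8))
  expect_equal(nrow(res$screenPredictions), 21L)
  nBeats <- sum(vapply(screens, function(s) nrow(featureMatrix(s)), numeric(1)))
  expect_equal(sum(counts(res$beatConfusion)), nBeats)

  # the design is enforced: dropping a screen needs the lenient flag
  expect_error(losoEvaluate(screens[-1], classifierConfig()), "strict")
  resL <- losoEvaluate(screens[-1], classifierConfig(seed = 2), requireStrict = FALSE)
  expect_equal(sum(counts(resL$sequenceConfusion)), 20)

  # fewer than 2 screens of a level cannot be cross-validated
  lv <- vapply(screens, function(s) beatLevels(s)[1], integer(1))
  drop2 <- screens[lv != 2 | seq_along(screens) == which(lv == 2)[1]]
  expect_error(losoEvaluate(drop2, requireStrict = FALSE), "at least 2")
})
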