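test_that("well-separated clusters are fit perfectly by the one-vs-rest margin classifier", {
  f <- makeClusterFeatures(nPerClass = 50, offset = 10, sd = 1, seed = 1)
  model <- trainWorkloadModel(f, classifierConfig("margin_ovr", seed = 3))
  sc <- scoreBeats(model, f)
  pred <- unname(apply(scoreMatrix(sc), 1, classifyBeat))
  expect_equal(pred, beatLevels(f))  # zero training misclassification

  # a point at class 2's centre: positive margin for 2, negative for 1 and 3
  midx <- matrix(0, 1, 10, dimnames = list(NULL, featureNamesForTag("c")))
  midx[1, 2] <- 10
  mid <- BeatFeatureMatrix(midx, "c", 1)
  s <- scoreMatrix(scoreBeats(model, mid))[1, ]
  expect_gt(s[2], 0)
  expect_lt(s[1], 0)
  expect_lt(s[3], 0)
})

test_that("tree-ensemble scores are vote proportions: rows in [0,1] summing to 1", {
  f <- makeClusterFeatures(nPerClass = 40, offset = 3, sd = 1.5, seed = 2)
  model <- trainWorkloadModel(f, classifierConfig("tree_ensemble", seed = 5))
  s <- scoreMatrix(scoreBeats(model, f))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(rowSums(s)), rep(1, nrow(s)))
  expect_equal(sum(classifySequence(s)$score), nrow(s))  # sequence scores sum to N
})

test_that("training refuses degenerate label sets and NaN features", {
  f <- makeClusterFeatures(seed = 3)
  beatLevels(f) <- rep(1L, nrow(featureMatrix(f)))
  expect_error(trainWorkloadModel(f), "absent")
  f2 <- makeClusterFeatures(seed = 3)
  beatLevels(f2) <- rep(c(1L, 3L), length.out = nrow(featureMatrix(f2)))
  expect_error(trainWorkloadModel(f2), "2")
  f3 <- makeClusterFeatures(seed = 3)
  f3@features[1, 1] <- NaN
  expect_error(trainWorkloadModel(f3), "NaN")
})

test_that("scoring checks the feature dimension against the trained model", {
  f <- makeClusterFeatures(seed = 4)
  model <- trainWorkloadModel(f, classifierConfig(seed = 1))
  wide <- BeatFeatureMatrix(matrix(0, 2, 30,
                                   dimnames = list(NULL, featureNamesForTag("c_da"))),
                            "c_da", 1:2)
  expect_error(scoreBeats(model, wide), "expects 10, got 30")
})

test_that("beat decisions take the argmax with least-negative-margin and tie rules", {
  expect_equal(classifyBeat(c(-0.2, -0.9, -1.4)), 1L)  # all negative: least negative
  expect_equal(classifyBeat(c(0.1, 0.5, 0.2)), 2L)
  expect_message(lv <- classifyBeat(c(0.4, 0.4, 0.1)), "tie")
  expect_equal(lv, 1L)  # ties break toward the lowest level
  expect_error(classifyBeat(c(1, NaN, 0)), "finite")
})

test_that("sequence decisions are column sums; one beat reduces to the beat decision", {
  y <- rbind(c(0.5, 0.1, 0.4))
  expect_equal(classifySequence(y)$level, classifyBeat(y[1, ]))

  y2 <- rbind(c(0.6, 1.7, 0.05), c(0.6, 1.7, 0.05))
  expect_equal(classifySequence(y2)$level, 2L)
  expect_equal(unname(classifySequence(y2)$score), c(1.2, 3.4, 0.1))

  set.seed(11)
  y3 <- matrix(rnorm(60), 20, 3)
  loopSums <- vapply(1:3, function(k) {
    s <- 0
    for (n in 1:20) s <- s + y3[n, k]
    s
  }, numeric(1))
  expect_equal(unname(classifySequence(y3)$score), loopSums, tolerance = 1e-12)
  expect_error(classifySequence(matrix(numeric(0), 0, 3)), "empty")
})

test_that("positive rescaling of margin scores never changes a decision", {
  set.seed(8)
  y <- matrix(rnorm(90), 30, 3)
  for (a in c(0.01, 1, 250)) {
    expect_equal(apply(a * y, 1, classifyBeat), apply(y, 1, classifyBeat))
    expect_equal(classifySequence(a * y)$level, classifySequence(y)$level)
  }
})

test_that("training and scoring are reproducible under a fixed seed", {
  f <- makeClusterFeatures(nPerClass = 30, offset = 2, sd = 2, seed = 6)
  s1 <- scoreMatrix(scoreBeats(trainWorkloadModel(f, classifierConfig("tree_ensemble", seed = 9)), f))
  s2 <- scoreMatrix(scoreBeats(trainWorkloadModel(f, classifierConfig("tree_ensemble", seed = 9)), f))
  expect_identical(s1, s2)
})

test_that("indistinguishable classes yield held-out accuracy at the trinary chance level", {
  set.seed(77)
  n <- 9000
  lv <- rep(1:3, length.out = n)
  x <- matrix(rnorm(n * 10), n, 10)
  colnames(x) <- featureNamesForTag("c")
  mk <- function(idx) {
    f <- BeatFeatureMatrix(x[idx, ], "c", seq_along(idx))
    beatLevels(f) <- lv[idx]
    f
  }
  train <- mk(1:6000)
  test <- mk(6001:9000)
  model <- trainWorkloadModel(train, classifierConfig("tree_ensemble", seed = 13))
  # vote-proportion ties are frequent with 100 trees; silence the tie log
  pred <- suppressMessages(apply(scoreMatrix(scoreBeats(model, test)), 1, classifyBeat))
  mcr <- 100 * mean(pred != beatLevels(test))
  expect_lt(abs(mcr - 200 / 3), 3)
})
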