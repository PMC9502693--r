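#' Classifier configuration
#'
#' Settings for the per-participant trinary classifiers. `margin_ovr`
#' trains three linear one-vs-rest maximum-margin binary classifiers on
#' standardized predictors; its soft score per class is the signed
#' distance from that class's decision boundary. `tree_ensemble` trains a
#' bootstrap ensemble of decision trees; its soft score is the proportion
#' of trees voting for each class.
#'
#' @param kind `"margin_ovr"` or `"tree_ensemble"`.
#' @param cost margin regularization strength (box constraint) for
#'   `margin_ovr`; default 1.
#' @param standardize standardize predictors with training-fold mean/sd
#'   (default on; the parameters are stored in the model and reused at
#'   scoring time).
#' @param nTrees number of trees for `tree_ensemble`; default 100.
#' @param minLeaf minimum observations in a leaf; default 1.
#' @param seed integer RNG seed used for training.
#' @return A list of class `classifierConfig`.
#' @export
classifierConfig <- function(kind = c("margin_ovr", "tree_ensemble"),
                             cost = 1, standardize = TRUE,
                             nTrees = 100L, minLeaf = 1L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(cost > 0, nTrees >= 1L, minLeaf >= 1L)
  structure(list(kind = kind, cost = cost, standardize = standardize,
                 nTrees = as.integer(nTrees), minLeaf = as.integer(minLeaf),
                 seed = as.integer(seed)),
            class = "classifierConfig")
}

.standardizeParams <- function(x, standardize) {
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1   # constant columns pass through
  } else {
    ctr <- rep(0, ncol(x))
    scl <- rep(1, ncol(x))
  }
  list(center = ctr, scale = scl)
}

.applyStandardize <- function(x, center, scale) {
  sweep(sweep(x, 2, center, "-"), 2, scale, "/")
}

#' Train a per-participant workload classifier
#'
#' Fits the configured trinary classifier on a labelled
#' [BeatFeatureMatrix-class]. All three workload levels must be present
#' in the training beats (each one-vs-rest classifier needs positive
#' examples). Standardization statistics are computed on the training
#' beats only and stored in the model.
#'
#' @param feats a [BeatFeatureMatrix-class] whose `beatLevels()` are set.
#' @param config a [classifierConfig()].
#' @return A [WorkloadModel-class].
#' @export
trainWorkloadModel <- function(feats, config = classifierConfig()) {
  stopifnot(is(feats, "BeatFeatureMatrix"), inherits(config, "classifierConfig"))
  x <- featureMatrix(feats)
  lv <- beatLevels(feats)
  if (!length(lv)) stop("training features must carry per-beat level labels",
                        call. = FALSE)
  if (anyNA(x) || !all(is.finite(x)))
    stop("training features contain NaN/Inf", call. = FALSE)
  present <- sort(unique(lv))
  if (!all(1:3 %in% present))
    stop(sprintf("level(s) %s absent from training data; cannot build their one-vs-rest classifier",
                 paste(setdiff(1:3, present), collapse = ", ")), call. = FALSE)
  std <- .standardizeParams(x, config$standardize)
  xs <- .applyStandardize(x, std$center, std$scale)
  oldSeed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, .GlobalEnv))
  set.seed(config$seed)
  if (config$kind == "margin_ovr") {
    fits <- lapply(1:3, function(k) {
      y <- factor(ifelse(lv == k, "pos", "neg"), levels = c("pos", "neg"))
      e1071::svm(xs, y, kernel = "linear", cost = config$cost,
                 scale = FALSE)
    })
  } else {
    fits <- list(randomForest::randomForest(
      xs, factor(lv, levels = 1:3),
      ntree = config$nTrees, nodesize = config$minLeaf))
  }
  new("WorkloadModel", kind = config$kind, fits = fits,
      center = std$center, scale = std$scale,
      tag = featureTag(feats), config = unclass(config))
}

#' Per-beat soft scores
#'
#' Scores every beat of a feature matrix with a trained model. For
#' `margin_ovr` column k holds the signed distance from classifier k's
#' decision boundary (positive inside class k's half-space); for
#' `tree_ensemble` it holds the proportion of trees voting for level k,
#' so each row sums to 1.
#'
#' @param model a [WorkloadModel-class].
#' @param feats a [BeatFeatureMatrix-class] with the same feature
#'   dimension the model was trained on.
#' @return A [SoftScoreMatrix-class] (N x 3).
#' @export
scoreBeats <- function(model, feats) {
  stopifnot(is(model, "WorkloadModel"), is(feats, "BeatFeatureMatrix"))
  x <- featureMatrix(feats)
  d <- length(model@center)
  if (ncol(x) != d)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 d, ncol(x)), call. = FALSE)
  xs <- .applyStandardize(x, model@center, model@scale)
  if (model@kind == "margin_ovr") {
    scores <- vapply(1:3, function(k) {
      p <- stats::predict(model@fits[[k]], xs, decision.values = TRUE)
      dv <- attr(p, "decision.values")
      # decision-value sign follows the label order in the column name
      if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
    }, numeric(nrow(xs)))
    if (nrow(xs) == 1L) scores <- matrix(scores, nrow = 1L)
  } else {
    scores <- stats::predict(model@fits[[1]], xs, type = "prob")
    scores <- scores[, as.character(1:3), drop = FALSE]
  }
  SoftScoreMatrix(scores, model@kind)
}

.argmaxLevel <- function(v) {
  m <- max(v)
  hits <- which(v == m)
  if (length(hits) > 1L)
    message(sprintf("score tie between levels %s; choosing level %d",
                    paste(hits, collapse = ", "), hits[1]))
  hits[1]
}

#' Beat-level decision from one score row
#'
#' The classified level is the argmax of the three soft scores. When all
#' margin scores are negative this automatically selects the class
#' closest to its decision boundary (least negative score). Exact ties
#' break toward the lowest level index and are reported via a message.
#'
#' @param scoreRow numeric 3-vector of finite soft scores.
#' @return Integer level in 1..3.
#' @export
#' @examples
#' classifyBeat(c(-0.2, -0.9, -1.4))  # 1: least negative margin
classifyBeat <- function(scoreRow) {
  if (length(scoreRow) != 3L || !all(is.finite(scoreRow)))
    stop("a score row must be 3 finite values", call. = FALSE)
  as.integer(.argmaxLevel(scoreRow))
}

#' Sequence-level decision from a score matrix
#'
#' The sequence (screen) soft score is the column sum of the per-beat
#' score matrix; the classified level is its argmax under the same tie
#' rule as [classifyBeat()]. With a single beat this reduces exactly to
#' the beat decision.
#'
#' @param scores a [SoftScoreMatrix-class] or numeric N x 3 matrix,
#'   N >= 1.
#' @return A list with `level` (integer) and `score` (named 3-vector of
#'   column sums).
#' @export
classifySequence <- function(scores) {
  s <- if (is(scores, "SoftScoreMatrix")) scoreMatrix(scores) else as.matrix(scores)
  if (nrow(s) < 1L) stop("empty score matrix", call. = FALSE)
  if (ncol(s) != 3L) stop("score matrix must have 3 columns", call. = FALSE)
  cs <- colSums(s)
  names(cs) <- .levelLabels
  list(level = as.integer(.argmaxLevel(cs)), score = cs)
}

## Fast row-wise argmax with the same lowest-index tie rule (max.col
## "first"); used in evaluation loops where per-row messages would flood.
.classifyBeats <- function(scores) {
  s <- if (is(scores, "SoftScoreMatrix")) scoreMatrix(scores) else scores
  max.col(s, ties.method = "first")
}
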