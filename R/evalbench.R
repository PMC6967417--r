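# Classifier bench: repeated stratified cross-validation, ranking of
# unlabeled pairs, and the standard binary-classification metrics.

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly drawn
#' positive outscores a uniformly drawn negative, with ties credited 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (1 = positive); both classes must be present.
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
#' @export
aucScore <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Accuracy, precision, recall and F1 at `scores >= threshold`. When no
#' positives are predicted, precision (and hence F1 when recall is also 0) is
#' reported as 0 with a warning.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector; both classes must be present.
#' @param threshold decision threshold (default 0.5).
#' @return named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
thresholdMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("metrics need both classes present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L); fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L); fn <- sum(pred == 0L & labels == 1L)
  precision <- if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0")
    0
  } else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = (tp + tn) / length(labels), precision = precision,
    recall = recall, f1 = f1)
}

#' Pinned classifier configurations
#'
#' The hyperparameters used for the three classifier specs, frozen here and
#' echoed into every [EvalReport-class]: gradient-boosted decision trees
#' (xgboost, binary logistic), random forest (ranger probability forest), and
#' a single-hidden-layer neural network (nnet).
#'
#' @return named list of per-classifier configuration lists.
#' @export
defaultClassifierConfig <- function() {
  list(
    gbdt = list(nrounds = 100, max_depth = 6, eta = 0.1,
                objective = "binary:logistic", nthread = 1,
                # exact greedy splits: histogram binning places thresholds at
                # sketch boundaries that hug the training values, misplacing
                # the decision boundary even across wide class margins
                tree_method = "exact"),
    rf = list(num.trees = 300, probability = TRUE),
    dnn = list(size = 64, decay = 1e-4, maxit = 200)
  )
}

# Fit one classifier and return a scoring closure emitting probabilities.
fitClassifier <- function(x, y, spec = c("gbdt", "rf", "dnn"), seed = 1L,
                          config = defaultClassifierConfig()) {
  spec <- match.arg(spec)
  cfg <- config[[spec]]
  if (spec == "gbdt") {
    set.seed(seed)
    dtr <- xgboost::xgb.DMatrix(x, label = y)
    fit <- xgboost::xgb.train(
      params = list(max_depth = cfg$max_depth, eta = cfg$eta,
                    objective = cfg$objective, nthread = cfg$nthread,
                    tree_method = cfg$tree_method, seed = seed),
      data = dtr, nrounds = cfg$nrounds, verbose = 0)
    function(newx) as.numeric(predict(fit, xgboost::xgb.DMatrix(newx)))
  } else if (spec == "rf") {
    xd <- as.data.frame(x)
    colnames(xd) <- paste0("f", seq_len(ncol(x)))
    xd$.y <- factor(y, levels = c(0, 1))
    fit <- ranger::ranger(dependent.variable.name = ".y", data = xd,
                          num.trees = cfg$num.trees, probability = TRUE,
                          seed = seed, num.threads = 1)
    function(newx) {
      nd <- as.data.frame(newx)
      colnames(nd) <- paste0("f", seq_len(ncol(newx)))
      as.numeric(predict(fit, nd, num.threads = 1)$predictions[, "1"])
    }
  } else {
    set.seed(seed)
    fit <- nnet::nnet(x, y, size = cfg$size, decay = cfg$decay,
                      maxit = cfg$maxit, entropy = TRUE, MaxNWts = 1e6,
                      trace = FALSE)
    function(newx) as.numeric(predict(fit, newx))
  }
}

# Stratified fold assignment: within each class, a shuffled round-robin.
stratifiedFolds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < folds)
      stop(sprintf("class %s has %d samples, fewer than %d folds",
                   cls, length(idx), folds))
    assign[sample(idx)] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified cross-validation of a classifier
#'
#' Runs `repeats` independent repetitions of stratified `folds`-fold
#' cross-validation (repeat r assigns folds with seed `seed + r - 1`), fits
#' the classifier on each training split and scores the held-out fold,
#' recording AUC plus thresholded accuracy/precision/recall/F1 per fold.
#' Aggregates are means over all `repeats x folds` records.
#'
#' @param features a [PairFeatures-class] or numeric matrix.
#' @param labels 0/1 vector, one per row.
#' @param classifier `"gbdt"`, `"rf"` or `"dnn"`.
#' @param folds,repeats protocol (defaults 5 and 10).
#' @param seed base seed for fold assignment and classifier fits.
#' @param config classifier hyperparameters, see
#'   [defaultClassifierConfig()].
#' @return an [EvalReport-class].
#' @export
runCV <- function(features, labels, classifier = c("gbdt", "rf", "dnn"),
                  folds = 5L, repeats = 10L, seed = 1L,
                  config = defaultClassifierConfig()) {
  classifier <- match.arg(classifier)
  stopifnot(folds >= 2L, repeats >= 1L)
  combo <- if (is(features, "PairFeatures")) features@combo else "custom"
  x <- if (is(features, "PairFeatures")) features@mat else features
  labels <- as.integer(labels)
  stopifnot(nrow(x) == length(labels))
  rows <- vector("list", repeats * folds)
  i <- 0L
  for (r in seq_len(repeats)) {
    assign <- stratifiedFolds(labels, folds, seed + r - 1L)
    for (f in seq_len(folds)) {
      test <- assign == f
      scorer <- fitClassifier(x[!test, , drop = FALSE], labels[!test],
                              classifier, seed = seed + r - 1L,
                              config = config)
      p <- scorer(x[test, , drop = FALSE])
      i <- i + 1L
      rows[[i]] <- data.frame(repeat_ = r, fold = f,
                              auc = aucScore(p, labels[test]),
                              t(thresholdMetrics(p, labels[test])))
    }
  }
  new("EvalReport", folds = do.call(rbind, rows), classifier = classifier,
      combo = combo,
      config = list(classifier = config[[classifier]],
                    protocol = list(folds = folds, repeats = repeats,
                                    seed = seed)))
}

#' Fit on a full training set and score new pairs
#'
#' @param featuresTrain,labelsTrain training rows (matrix or
#'   [PairFeatures-class]) and 0/1 labels.
#' @param featuresScore rows to score; must have the same number of columns.
#' @param classifier `"gbdt"`, `"rf"` or `"dnn"`.
#' @param seed classifier seed.
#' @param config see [defaultClassifierConfig()].
#' @return numeric vector of probabilities in [0, 1].
#' @export
trainFullAndScore <- function(featuresTrain, labelsTrain, featuresScore,
                              classifier = c("gbdt", "rf", "dnn"), seed = 1L,
                              config = defaultClassifierConfig()) {
  classifier <- match.arg(classifier)
  xtr <- if (is(featuresTrain, "PairFeatures")) featuresTrain@mat else
    featuresTrain
  xsc <- if (is(featuresScore, "PairFeatures")) featuresScore@mat else
    featuresScore
  if (ncol(xtr) != ncol(xsc))
    stop(sprintf("feature dimension mismatch: train %d vs score %d",
                 ncol(xtr), ncol(xsc)))
  labelsTrain <- as.integer(labelsTrain)
  if (!any(labelsTrain == 1L) || !any(labelsTrain == 0L))
    stop("training labels must contain both classes")
  scorer <- fitClassifier(xtr, labelsTrain, classifier, seed = seed,
                          config = config)
  pmin(pmax(scorer(xsc), 0), 1)
}

#' Rank unlabeled pairs by predicted interaction probability
#'
#' Sorts pairs by descending probability; exact ties are broken by
#' (drug_id, target_id) lexicographic order for determinism.
#'
#' @param probabilities numeric scores, one per pair.
#' @param pairIds data.frame with columns `drug_id`, `target_id`.
#' @param topN how many pairs to return.
#' @return data.frame `rank`, `drug_id`, `target_id`, `probability`.
#' @export
rankUnlabeled <- function(probabilities, pairIds, topN = 5L) {
  stopifnot(nrow(pairIds) == length(probabilities),
            topN <= length(probabilities))
  ord <- order(-probabilities, pairIds$drug_id, pairIds$target_id,
               method = "radix")
  take <- ord[seq_len(topN)]
  data.frame(rank = seq_len(topN), drug_id = pairIds$drug_id[take],
             target_id = pairIds$target_id[take],
             probability = probabilities[take])
}
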