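# Skip-gram with negative sampling (SGNS). The heavy SGD loop lives in
# src/skipgram.cpp; the objective, gradients and negative sampler are also
# exposed in R so they can be tested against brute-force oracles.

#' @useDynLib spvec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Skip-gram training hyperparameters
#'
#' Defaults follow the method's published settings: embedding dimension
#' d = 100, context window c = 12, k = 15 negative samples per positive pair.
#' The optimizer is plain SGD with a linear learning-rate ramp from `lrStart`
#' to `lrEnd` over all scheduled updates; negatives are drawn from the
#' unigram distribution raised to the 3/4 power unless `negDistribution =
#' "uniform"`.
#'
#' @param dim embedding dimension m (default 100).
#' @param window context half-width c (default 12).
#' @param negatives negative samples k per (center, context) pair (default
#'   15).
#' @param epochs training passes over the corpus (default 5; 0 returns the
#'   untouched random initialization).
#' @param lrStart,lrEnd linear learning-rate schedule endpoints (defaults
#'   0.025 and 1e-4).
#' @param negDistribution `"unigram_pow_0.75"` (default) or `"uniform"`.
#' @param minCount vocabulary count threshold (default 1).
#' @param seed integer seed; training is single-threaded and bit-reproducible
#'   given (corpus, params, seed).
#' @return a validated named list of parameters.
#' @export
skipGramParams <- function(dim = 100L, window = 12L, negatives = 15L,
                           epochs = 5L, lrStart = 0.025, lrEnd = 1e-4,
                           negDistribution = c("unigram_pow_0.75", "uniform"),
                           minCount = 1L, seed = 1L) {
  negDistribution <- match.arg(negDistribution)
  p <- list(dim = as.integer(dim), window = as.integer(window),
            negatives = as.integer(negatives), epochs = as.integer(epochs),
            lrStart = lrStart, lrEnd = lrEnd,
            negDistribution = negDistribution,
            minCount = as.integer(minCount), seed = as.integer(seed))
  stopifnot(p$dim >= 1L, p$window >= 1L, p$negatives >= 1L, p$epochs >= 0L,
            p$lrStart > p$lrEnd, p$lrEnd > 0)
  p
}

#' Numerically stable logistic function
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, computed without overflow for any
#' finite argument (the argument is clamped at +-700 where the result is
#' already 0 or 1 to double precision).
#'
#' @param x numeric vector.
#' @return values in (0, 1).
#' @export
sigmoid <- function(x) {
  x <- pmin(pmax(x, -700), 700)
  ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))
}

#' Negative-sampling distribution of a vocabulary
#'
#' @param vocab a [Vocabulary-class].
#' @param negDistribution `"unigram_pow_0.75"` (counts raised to 3/4,
#'   normalized) or `"uniform"`.
#' @return numeric probability vector over vocabulary indices.
#' @export
negSamplingProbs <- function(vocab,
                             negDistribution = c("unigram_pow_0.75", "uniform")) {
  negDistribution <- match.arg(negDistribution)
  n <- vocabSize(vocab)
  if (negDistribution == "uniform") return(rep(1 / n, n))
  w <- vocab@counts^0.75
  w / sum(w)
}

#' Draw k negative-sample indices
#'
#' Draws `k` vocabulary indices i.i.d. from the configured negative-sampling
#' distribution, redrawing any index that collides with `exclude` (the
#' positive target word). Uses R's RNG: seed with `set.seed()` for
#' reproducibility.
#'
#' @param vocab a [Vocabulary-class] with at least 2 tokens.
#' @param k number of negatives (default 15).
#' @param exclude 1-based vocabulary index never to return.
#' @param negDistribution see [negSamplingProbs()].
#' @return integer vector of `k` 1-based vocabulary indices.
#' @export
drawNegatives <- function(vocab, k = 15L, exclude,
                          negDistribution = c("unigram_pow_0.75", "uniform")) {
  if (vocabSize(vocab) < 2L) stop("need at least 2 vocabulary tokens")
  probs <- negSamplingProbs(vocab, negDistribution)
  out <- integer(0)
  while (length(out) < k) {
    draw <- sample.int(vocabSize(vocab), k - length(out), replace = TRUE,
                       prob = probs)
    out <- c(out, draw[draw != exclude])
  }
  out
}

dotProduct <- function(model, centerIdx, targetIdx) {
  sum(model@inputVectors[centerIdx, ] * model@outputVectors[targetIdx, ])
}

#' Log-likelihood of one labeled (center, target) pair
#'
#' The per-pair term of the negative-sampling objective:
#' `log sigma(V(center) . theta(target))` for a positive pair (label 1) and
#' `log(1 - sigma(.))` for a drawn negative (label 0). The dot product is
#' clamped at +-35 and the log floored at `log(1e-15)`, matching the trainer,
#' so the value is always finite and <= 0.
#'
#' @param model a [SkipGramModel-class].
#' @param centerIdx,targetIdx 1-based vocabulary indices of the center word
#'   and the (positive or negative) target word.
#' @param label 1 for the true context word, 0 for a negative sample.
#' @return a single non-positive finite number.
#' @export
pairObjective <- function(model, centerIdx, targetIdx, label) {
  stopifnot(label %in% c(0, 1))
  s <- sigmoid(pmin(pmax(dotProduct(model, centerIdx, targetIdx), -35), 35))
  p <- if (label == 1) s else 1 - s
  log(max(p, 1e-15))
}

#' Analytic gradients of the pair objective
#'
#' For `p = sigma(V(center) . theta(target))` and label L, the gradient of
#' the log-likelihood is `(L - p) * theta(target)` with respect to the center
#' word's input vector and `(L - p) * V(center)` with respect to the target
#' word's output vector.
#'
#' @inheritParams pairObjective
#' @return list with components `dInput` (gradient wrt V(center)) and
#'   `dOutput` (gradient wrt theta(target)).
#' @export
pairGradients <- function(model, centerIdx, targetIdx, label) {
  stopifnot(label %in% c(0, 1))
  g <- label - sigmoid(dotProduct(model, centerIdx, targetIdx))
  list(dInput = g * model@outputVectors[targetIdx, ],
       dOutput = g * model@inputVectors[centerIdx, ])
}

#' Freeze negative draws for deterministic objective evaluation
#'
#' Enumerates every (center, context) pair of the corpus (tokens below the
#' vocabulary's threshold are skipped) and pre-draws `k` negatives for each,
#' so that [corpusObjective()] is a deterministic function of the model.
#'
#' @param corpus a [Corpus-class].
#' @param vocab the [Vocabulary-class] used by the model.
#' @param window context half-width.
#' @param k negatives per pair.
#' @param seed RNG seed for the draws.
#' @param negDistribution see [negSamplingProbs()].
#' @return list with `centers`, `contexts` (integer vectors of 1-based
#'   indices) and `negatives` (n_pairs x k integer matrix).
#' @export
freezeNegatives <- function(corpus, vocab, window = 12L, k = 15L, seed = 1L,
                            negDistribution = c("unigram_pow_0.75", "uniform")) {
  negDistribution <- match.arg(negDistribution)
  idxSentences <- corpusIndices(corpus, vocab)
  centers <- integer(); contexts <- integer()
  for (s in idxSentences) {
    n <- length(s)
    if (n < 2L) next
    for (i in seq_len(n)) {
      j <- setdiff(max(1L, i - window):min(n, i + window), i)
      centers <- c(centers, rep.int(s[i], length(j)))
      contexts <- c(contexts, s[j])
    }
  }
  set.seed(seed)
  negs <- matrix(0L, nrow = length(centers), ncol = k)
  for (r in seq_along(centers))
    negs[r, ] <- drawNegatives(vocab, k, contexts[r], negDistribution)
  list(centers = centers, contexts = contexts, negatives = negs)
}

# Map corpus sentences to 1-based vocabulary index vectors, dropping
# out-of-vocabulary tokens (those removed by min_count).
corpusIndices <- function(corpus, vocab) {
  lapply(corpus@sentences, function(s) {
    idx <- match(s, vocab@tokens)
    idx[!is.na(idx)]
  })
}

#' Full-corpus negative-sampling objective with frozen negatives
#'
#' Sums the pair log-likelihood over every (center, context) pair of the
#' corpus and, for each, over its pre-drawn negative samples: the quantity
#' the SGD trainer ascends, made deterministic by freezing the draws.
#'
#' @param model a [SkipGramModel-class].
#' @param frozen the draw set from [freezeNegatives()].
#' @return a single finite number (<= 0).
#' @export
corpusObjective <- function(model, frozen) {
  Vin <- model@inputVectors; Vout <- model@outputVectors
  dots <- rowSums(Vin[frozen$centers, , drop = FALSE] *
                  Vout[frozen$contexts, , drop = FALSE])
  s <- sigmoid(pmin(pmax(dots, -35), 35))
  total <- sum(log(pmax(s, 1e-15)))
  k <- ncol(frozen$negatives)
  for (col in seq_len(k)) {
    dots <- rowSums(Vin[frozen$centers, , drop = FALSE] *
                    Vout[frozen$negatives[, col], , drop = FALSE])
    s <- sigmoid(pmin(pmax(dots, -35), 35))
    total <- total + sum(log(pmax(1 - s, 1e-15)))
  }
  total
}

#' Train a Skip-gram model with negative sampling
#'
#' Builds the vocabulary (unless one is supplied), converts sentences to
#' index vectors (out-of-vocabulary tokens dropped), and runs single-threaded
#' SGD: sentences are shuffled each epoch with the run seed, every (center,
#' context) pair within the fixed window receives one positive update and
#' `negatives` negative updates, and the learning rate decays linearly over
#' all scheduled updates. Training is bit-reproducible given (corpus, params,
#' seed). With `epochs = 0` the returned model holds the untouched random
#' initialization (useful as a pre-training baseline).
#'
#' @param corpus a [Corpus-class].
#' @param params a list from [skipGramParams()].
#' @param vocab optional pre-built [Vocabulary-class].
#' @return a [SkipGramModel-class].
#' @examples
#' corp <- smilesCorpus(c(a = "CCO", b = "CCN", d = "c1ccccc1"))
#' m <- trainSkipGram(corp, skipGramParams(dim = 8, window = 2, negatives = 3,
#'                                         epochs = 2, seed = 7))
#' dim(inputVectors(m))
#' @export
trainSkipGram <- function(corpus, params = skipGramParams(), vocab = NULL) {
  stopifnot(is(corpus, "Corpus"))
  if (length(corpus@sentences) == 0L) stop("corpus is empty")
  if (is.null(vocab)) vocab <- buildVocab(corpus, params$minCount)
  idx0 <- lapply(corpusIndices(corpus, vocab), function(s) s - 1L)
  probs <- negSamplingProbs(vocab, params$negDistribution)
  fit <- .sgnsTrain(idx0, vocabSize(vocab), params$dim, params$window,
                    params$negatives, params$epochs, params$lrStart,
                    params$lrEnd, probs, as.double(params$seed))
  new("SkipGramModel", vocab = vocab, inputVectors = fit$input,
      outputVectors = fit$output, params = params)
}
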