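# Small deterministic model for objective/gradient tests.
tinyModel <- function(nv = 4, dim = 3, seed = 5, zeroOutput = FALSE) {
  set.seed(seed)
  vocab <- new("Vocabulary", tokens = LETTERS[1:nv],
               counts = rev(seq_len(nv)) + 1, minCount = 1L)
  new("SkipGramModel", vocab = vocab,
      inputVectors = matrix(rnorm(nv * dim, sd = 0.3), nv, dim),
      outputVectors = if (zeroOutput) matrix(0, nv, dim) else
        matrix(rnorm(nv * dim, sd = 0.3), nv, dim),
      params = skipGramParams(dim = dim, window = 2, negatives = 2,
                              epochs = 1))
}

test_that("sigmoid is exact at 0, symmetric, and stable at extremes", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-20, -3.3, 0.1, 7, 120)
  expect_equal(sigmoid(x), 1 - sigmoid(-x), tolerance = 1e-12)
  expect_equal(sigmoid(35), 1 / (1 + exp(-35)), tolerance = 1e-12)
  expect_equal(sigmoid(1000), 1)
  expect_equal(sigmoid(-1000), 0)
})

test_that("negative draws respect count, exclusion and the 3/4-power law", {
  vocab <- new("Vocabulary", tokens = c("a", "b", "c", "d", "e"),
               counts = c(100, 50, 20, 10, 5), minCount = 1L)
  set.seed(1)
  d <- drawNegatives(vocab, 15, exclude = 2)
  expect_length(d, 15)
  expect_false(2 %in% d)
  expect_error(drawNegatives(new("Vocabulary", tokens = "a", counts = 3,
                                 minCount = 1L), 5, 1), "at least 2")
  # empirical frequencies vs the count^0.75 law conditioned on the exclusion
  set.seed(99)
  draws <- drawNegatives(vocab, 1e5, exclude = 2)
  p <- vocabCounts(vocab)^0.75
  p <- p / sum(p)
  cond <- p[-2] / sum(p[-2])
  obs <- tabulate(draws, 5)[-2]
  expect_gt(stats::chisq.test(obs, p = cond)$p.value, 0.01)
})

test_that("pair objective matches hand and oracle computations", {
  m <- tinyModel(zeroOutput = TRUE)
  expect_equal(pairObjective(m, 1, 2, 1), log(0.5))
  expect_equal(pairObjective(m, 1, 2, 0), log(0.5))
  # random small model vs direct recomputation from the matrices
  m2 <- tinyModel(seed = 11)
  for (case in list(c(1, 3, 1), c(2, 4, 0), c(4, 1, 1))) {
    dot <- sum(inputVectors(m2)[case[1], ] * outputVectors(m2)[case[2], ])
    p <- 1 / (1 + exp(-dot))
    expected <- if (case[3] == 1) log(p) else log(1 - p)
    expect_equal(pairObjective(m2, case[1], case[2], case[3]), expected,
                 tolerance = 1e-12)
  }
})

test_that("analytic gradients match plug-in forms and finite differences", {
  m <- tinyModel(zeroOutput = TRUE)
  g <- pairGradients(m, 2, 3, 1)
  expect_equal(g$dOutput, 0.5 * m@inputVectors[2, ])  # sigma = 0.5 at dot 0
  mZeroIn <- initialize(m, inputVectors = matrix(0, 4, 3))
  expect_equal(pairGradients(mZeroIn, 2, 3, 1)$dOutput, rep(0, 3))

  # central finite differences of the objective at 10 random points
  set.seed(21)
  h <- 1e-6
  for (rep_ in 1:10) {
    m2 <- tinyModel(seed = 100 + rep_)
    ci <- sample(4, 1); ti <- sample(4, 1); lab <- sample(0:1, 1)
    g2 <- pairGradients(m2, ci, ti, lab)
    for (d in 1:3) {
      up <- m2; up@inputVectors[ci, d] <- up@inputVectors[ci, d] + h
      dn <- m2; dn@inputVectors[ci, d] <- dn@inputVectors[ci, d] - h
      fd <- (pairObjective(up, ci, ti, lab) -
             pairObjective(dn, ci, ti, lab)) / (2 * h)
      expect_equal(g2$dInput[d], fd, tolerance = 1e-5)
      up <- m2; up@outputVectors[ti, d] <- up@outputVectors[ti, d] + h
      dn <- m2; dn@outputVectors[ti, d] <- dn@outputVectors[ti, d] - h
      fd <- (pairObjective(up, ci, ti, lab) -
             pairObjective(dn, ci, ti, lab)) / (2 * h)
      expect_equal(g2$dOutput[d], fd, tolerance = 1e-5)
    }
  }
})

test_that("corpus objective equals closed form and brute-force enumeration", {
  corp <- smilesCorpus(c("CCO", "OCN"))
  vocab <- buildVocab(corp)
  frozen <- freezeNegatives(corp, vocab, window = 2, k = 3, seed = 4)
  nPairs <- length(frozen$centers)
  # all-zero output vectors: every factor is sigma(0) = 1/2
  m0 <- new("SkipGramModel", vocab = vocab,
            inputVectors = matrix(0.3, vocabSize(vocab), 3),
            outputVectors = matrix(0, vocabSize(vocab), 3),
            params = skipGramParams(dim = 3))
  expect_equal(corpusObjective(m0, frozen), nPairs * 4 * log(0.5))
  # random model vs the independent product-then-log oracle
  set.seed(8)
  mr <- initialize(m0,
    inputVectors = matrix(rnorm(vocabSize(vocab) * 3), ncol = 3),
    outputVectors = matrix(rnorm(vocabSize(vocab) * 3), ncol = 3))
  expect_equal(corpusObjective(mr, frozen), bruteCorpusObjective(mr, frozen),
               tolerance = 1e-10)
  expect_true(is.finite(corpusObjective(mr, frozen)))
})

test_that("training is bit-reproducible given the seed", {
  corp <- syntheticTokenCorpus(2, 15, c(8, 15), seed = 2)
  p <- skipGramParams(dim = 12, window = 3, negatives = 4, epochs = 2,
                      seed = 31)
  m1 <- trainSkipGram(corp, p)
  m2 <- trainSkipGram(corp, p)
  expect_identical(m1@inputVectors, m2@inputVectors)
  expect_identical(m1@outputVectors, m2@outputVectors)
  m3 <- trainSkipGram(corp, skipGramParams(dim = 12, window = 3,
                                           negatives = 4, epochs = 2,
                                           seed = 32))
  expect_false(identical(m1@inputVectors, m3@inputVectors))
})

test_that("SGD increases the frozen-negative objective", {
  corp <- syntheticTokenCorpus(2, 25, c(10, 18), seed = 6)
  vocab <- buildVocab(corp)
  p <- skipGramParams(dim = 16, window = 4, negatives = 5, epochs = 5,
                      seed = 3)
  frozen <- freezeNegatives(corp, vocab, window = 4, k = 5, seed = 13)
  before <- corpusObjective(trainSkipGram(corp, modifyList(p, list(epochs = 0L)),
                                          vocab = vocab), frozen)
  after <- corpusObjective(trainSkipGram(corp, p, vocab = vocab), frozen)
  expect_gt(after, before)
})

test_that("disjoint token groups become separated in embedding space", {
  corp <- syntheticTokenCorpus(2, 40, c(12, 20), classTokenRate = 0.6,
                               seed = 17)
  m <- trainSkipGram(corp, skipGramParams(dim = 24, window = 5,
                                          negatives = 5, epochs = 5,
                                          seed = 17))
  emb <- inputVectors(m)
  g1 <- emb[rownames(emb) %in% c("S", "Cl", "[NH3+]"), , drop = FALSE]
  g2 <- emb[rownames(emb) %in% c("P", "Br", "[O-]"), , drop = FALSE]
  meanCos <- function(A, B) {
    A <- A / sqrt(rowSums(A^2)); B <- B / sqrt(rowSums(B^2))
    mean(tcrossprod(A, B))
  }
  within <- (meanCos(g1, g1) + meanCos(g2, g2)) / 2
  expect_gt(within, meanCos(g1, g2))
})

test_that("an independent plain-R trainer recovers the same cluster structure", {
  corp <- syntheticTokenCorpus(2, 40, c(12, 20), classTokenRate = 0.6,
                               seed = 23)
  vocab <- buildVocab(corp)
  m <- trainSkipGram(corp, skipGramParams(dim = 16, window = 4,
                                          negatives = 5, epochs = 5,
                                          seed = 23), vocab = vocab)
  ref <- refSgnsTrain(corp@sentences, vocabTokens(vocab), dim = 16,
                      window = 4, k = 5, epochs = 5, seed = 23)
  classTokens <- list(c("S", "Cl", "[NH3+]"), c("P", "Br", "[O-]"))
  tokenClass <- function(t)
    if (t %in% classTokens[[1]]) 1L else if (t %in% classTokens[[2]]) 2L else NA
  queries <- intersect(unlist(classTokens), vocabTokens(vocab))
  nnClass <- function(emb, q) {
    d <- apply(emb, 1, function(r)
      1 - sum(emb[q, ] * r) / sqrt(sum(emb[q, ]^2) * sum(r^2)))
    d[q] <- Inf
    cand <- names(sort(d))
    cls <- vapply(cand, tokenClass, integer(1))
    cls[!is.na(cls)][1]  # class of the nearest class-bearing token
  }
  agree <- vapply(queries, function(q)
    nnClass(inputVectors(m), q) == nnClass(ref, q) &&
      nnClass(inputVectors(m), q) == tokenClass(q), logical(1))
  expect_gte(mean(agree), 0.6)
})
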