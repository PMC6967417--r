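# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# AUC as the explicit count of concordant positive-negative pairs (ties 1/2).
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Exhaustive cosine-distance sort (ties by id), excluding the query.
bruteNeighbors <- function(mat, ids, queryId, k) {
  qi <- match(queryId, ids)
  q <- mat[qi, ]
  d <- apply(mat, 1, function(r)
    1 - sum(q * r) / sqrt(sum(q^2) * sum(r^2)))
  d[qi] <- Inf
  ord <- order(d, ids, method = "radix")
  data.frame(id = ids[ord[1:k]], cosine_distance = d[ord[1:k]])
}

# Corpus objective by direct product-then-log enumeration over pairs.
bruteCorpusObjective <- function(model, frozen) {
  Vin <- inputVectors(model); Vout <- outputVectors(model)
  sig <- function(x) 1 / (1 + exp(-min(max(x, -35), 35)))
  total <- 0
  for (r in seq_along(frozen$centers)) {
    g <- sig(sum(Vin[frozen$centers[r], ] * Vout[frozen$contexts[r], ]))
    for (neg in frozen$negatives[r, ])
      g <- g * (1 - sig(sum(Vin[frozen$centers[r], ] * Vout[neg, ])))
    total <- total + log(max(g, .Machine$double.xmin))
  }
  total
}

# Tiny plain-R skip-gram/negative-sampling trainer: a from-first-principles
# reference, sharing no code (or RNG stream) with the package's trainer.
refSgnsTrain <- function(sentences, vocabTokens, dim = 16, window = 4,
                         k = 5, epochs = 5, lr = 0.05, seed = 1) {
  set.seed(seed)
  nv <- length(vocabTokens)
  vin <- matrix(runif(nv * dim, -0.5, 0.5) / dim, nv, dim)
  vout <- matrix(0, nv, dim)
  sig <- function(x) 1 / (1 + exp(-min(max(x, -35), 35)))
  idxSent <- lapply(sentences, function(s) match(s, vocabTokens))
  for (e in seq_len(epochs)) {
    for (s in idxSent) {
      n <- length(s)
      for (i in seq_len(n)) {
        for (j in setdiff(max(1, i - window):min(n, i + window), i)) {
          center <- s[i]; u <- s[j]
          targets <- c(u, sample(setdiff(seq_len(nv), u), k, replace = TRUE))
          labels <- c(1, rep(0, k))
          acc <- numeric(dim)
          for (t in seq_along(targets)) {
            g <- (labels[t] - sig(sum(vin[center, ] * vout[targets[t], ]))) * lr
            acc <- acc + g * vout[targets[t], ]
            vout[targets[t], ] <- vout[targets[t], ] + g * vin[center, ]
          }
          vin[center, ] <- vin[center, ] + acc
        }
      }
    }
  }
  rownames(vin) <- vocabTokens
  vin
}

# Rule-by-rule temporal classification of one interaction, written straight
# from the five dataset definitions.
bruteTemporalBucket <- function(drugDate, targetDate, pairDate, cutoff) {
  dOld <- drugDate < cutoff
  tOld <- targetDate < cutoff
  if (dOld && tOld) { if (pairDate < cutoff) 1L else 2L }
  else if (!dOld && tOld) 3L
  else if (dOld && !tOld) 4L
  else 5L
}

# Small two-cluster feature block with a guaranteed margin: class 0 features
# lie in [0, 1] and class 1 features in [gap, gap + 1], so any split inside
# the empty (1, gap) band separates the classes exactly.
separableBlock <- function(nPerClass = 60, p = 10, gap = 6, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(runif(nPerClass * p), ncol = p),
             matrix(runif(nPerClass * p, min = gap, max = gap + 1), ncol = p))
  list(x = x, y = rep(c(0L, 1L), each = nPerClass))
}
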