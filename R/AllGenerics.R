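#' @rdname accessors
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @rdname accessors
#' @export
setGeneric("vocabTokens", function(x) standardGeneric("vocabTokens"))

#' @rdname accessors
#' @export
setGeneric("vocabCounts", function(x) standardGeneric("vocabCounts"))

#' @rdname accessors
#' @export
setGeneric("tokenIndex", function(x, tokens) standardGeneric("tokenIndex"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureScheme", function(x) standardGeneric("featureScheme"))

#' @rdname accessors
#' @export
setGeneric("inputVectors", function(x) standardGeneric("inputVectors"))

#' @rdname accessors
#' @export
setGeneric("outputVectors", function(x) standardGeneric("outputVectors"))

#' @rdname accessors
#' @export
setGeneric("modelVocab", function(x) standardGeneric("modelVocab"))

#' @rdname accessors
#' @export
setGeneric("modelParams", function(x) standardGeneric("modelParams"))

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @rdname accessors
#' @export
setGeneric("drugs", function(x) standardGeneric("drugs"))

#' @rdname accessors
#' @export
setGeneric("targets", function(x) standardGeneric("targets"))

#' @rdname accessors
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname accessors
#' @export
setGeneric("aggregateMetrics", function(x) standardGeneric("aggregateMetrics"))

# ---- accessors -------------------------------------------------------------

#' Accessors for spvec S4 classes
#'
#' Small accessor generics so user code never touches slots directly:
#' vocabulary size/tokens/counts and token-to-index lookup, feature-block
#' ids/matrix/scheme, model matrices, dataset components, and per-fold or
#' aggregated metrics of an evaluation report.
#'
#' @param x the object.
#' @param tokens character vector of tokens to look up; unknown tokens give
#'   `NA`.
#' @return The requested component. `tokenIndex` returns 1-based positions in
#'   the vocabulary's deterministic order. `aggregateMetrics` returns a
#'   data.frame with one row per metric (mean and sd over all folds).
#' @name accessors
#' @aliases vocabSize vocabTokens vocabCounts tokenIndex featureIds
#'   featureMatrix featureScheme inputVectors outputVectors modelVocab
#'   modelParams interactions drugs targets foldMetrics aggregateMetrics
NULL

#' @rdname accessors
#' @export
setMethod("vocabSize", "Vocabulary", function(x) length(x@tokens))

#' @rdname accessors
#' @export
setMethod("vocabTokens", "Vocabulary", function(x) x@tokens)

#' @rdname accessors
#' @export
setMethod("vocabCounts", "Vocabulary",
          function(x) stats::setNames(x@counts, x@tokens))

#' @rdname accessors
#' @export
setMethod("tokenIndex", "Vocabulary",
          function(x, tokens) match(tokens, x@tokens))

#' @rdname accessors
#' @export
setMethod("featureIds", "FeatureBlock", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureBlock", function(x) {
  m <- x@mat
  rownames(m) <- x@ids
  m
})

#' @rdname accessors
#' @export
setMethod("featureScheme", "FeatureBlock", function(x) x@scheme)

#' @rdname accessors
#' @export
setMethod("featureMatrix", "PairFeatures", function(x) x@mat)

#' @rdname accessors
#' @export
setMethod("featureIds", "PairFeatures",
          function(x) data.frame(drug_id = x@drugIds, target_id = x@targetIds))

#' @rdname accessors
#' @export
setMethod("inputVectors", "SkipGramModel", function(x) {
  m <- x@inputVectors
  rownames(m) <- x@vocab@tokens
  m
})

#' @rdname accessors
#' @export
setMethod("outputVectors", "SkipGramModel", function(x) {
  m <- x@outputVectors
  rownames(m) <- x@vocab@tokens
  m
})

#' @rdname accessors
#' @export
setMethod("modelVocab", "SkipGramModel", function(x) x@vocab)

#' @rdname accessors
#' @export
setMethod("modelParams", "SkipGramModel", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("interactions", "DTIDataset", function(x) x@interactions)

#' @rdname accessors
#' @export
setMethod("drugs", "DTIDataset", function(x) x@drugs)

#' @rdname accessors
#' @export
setMethod("targets", "DTIDataset", function(x) x@targets)

#' @rdname accessors
#' @export
setMethod("foldMetrics", "EvalReport", function(x) x@folds)

#' @rdname accessors
#' @export
setMethod("aggregateMetrics", "EvalReport", function(x) {
  metrics <- c("auc", "accuracy", "precision", "recall", "f1")
  data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(x@folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(x@folds[[m]]), numeric(1)),
    row.names = NULL
  )
})

# ---- show ------------------------------------------------------------------

setMethod("show", "Corpus", function(object) {
  cat(sprintf("Corpus of %d %s sentence(s), %d tokens total\n",
              length(object@sentences), object@kind,
              sum(lengths(object@sentences))))
})

setMethod("show", "Vocabulary", function(object) {
  cat(sprintf("Vocabulary: %d tokens (min_count = %d)\n",
              length(object@tokens), object@minCount))
  if (length(object@tokens)) {
    k <- min(5L, length(object@tokens))
    cat("  top:", paste(sprintf("%s(%d)", object@tokens[seq_len(k)],
                                object@counts[seq_len(k)]), collapse = " "), "\n")
  }
})

setMethod("show", "SkipGramModel", function(object) {
  cat(sprintf("SkipGramModel: |V| = %d, dim = %d (window %d, negatives %d)\n",
              nrow(object@inputVectors), ncol(object@inputVectors),
              object@params$window, object@params$negatives))
})

setMethod("show", "FeatureBlock", function(object) {
  cat(sprintf("FeatureBlock '%s': %d records x %d features\n",
              object@scheme, nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "PairFeatures", function(object) {
  cat(sprintf("PairFeatures '%s': %d pairs x %d features\n",
              object@combo, nrow(object@mat), ncol(object@mat)))
})

setMethod("show", "DTIDataset", function(object) {
  lab <- table(factor(object@interactions$label,
                      c("positive", "negative", "unlabeled")))
  cat(sprintf("DTIDataset '%s': %d drugs, %d targets, %d interactions (%s)\n",
              object@name, nrow(object@drugs), length(object@targets),
              nrow(object@interactions),
              paste(sprintf("%s %d", names(lab), lab), collapse = ", ")))
})

setMethod("show", "EvalReport", function(object) {
  agg <- aggregateMetrics(object)
  cat(sprintf("EvalReport %s / %s over %d folds\n", object@combo,
              object@classifier, nrow(object@folds)))
  cat(paste(sprintf("  %-9s %.4f (sd %.4f)", agg$metric, agg$mean, agg$sd),
            collapse = "\n"), "\n")
})

setMethod("show", "ProjectedCloud", function(object) {
  cat(sprintf("ProjectedCloud: %d points in %d-D%s\n", length(object@ids),
              ncol(object@coords),
              if (length(object@color)) ", colored" else ""))
})
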