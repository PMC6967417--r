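#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats runif rnorm sd predict setNames dist
#' @importFrom utils head read.delim write.table capture.output
NULL

#' Tokenized corpus
#'
#' A homogeneous collection of tokenized "sentences": either SMILES strings
#' split into atom-aware tokens, or protein sequences split into
#' non-overlapping amino-acid 3-mer words. Each sentence keeps the identifier
#' of the record it came from (one record can yield several sentences, e.g.
#' the three reading frames of a protein).
#'
#' @slot sentences list of character vectors, one per sentence.
#' @slot ids character vector of source record identifiers, parallel to
#'   `sentences`.
#' @slot kind `"smiles"` or `"protein"`.
#' @export
setClass("Corpus", representation(
  sentences = "list",
  ids = "character",
  kind = "character"
))

setValidity("Corpus", function(object) {
  if (length(object@sentences) != length(object@ids))
    return("sentences and ids must have the same length")
  if (!object@kind %in% c("smiles", "protein"))
    return("kind must be 'smiles' or 'protein'")
  if (!all(vapply(object@sentences, is.character, logical(1))))
    return("every sentence must be a character vector")
  TRUE
})

#' Token vocabulary
#'
#' The discrete dictionary over which Skip-gram embeddings are trained.
#' Tokens are stored in a fixed deterministic order (descending count, ties
#' broken lexicographically); a token's index is its position in that order.
#'
#' @slot tokens character vector, the dictionary in index order.
#' @slot counts numeric vector of corpus occurrence counts, parallel to
#'   `tokens`; every stored count is `>= minCount`.
#' @slot minCount integer, the count threshold applied when building.
#' @export
setClass("Vocabulary", representation(
  tokens = "character",
  counts = "numeric",
  minCount = "integer"
))

setValidity("Vocabulary", function(object) {
  if (length(object@tokens) != length(object@counts))
    return("tokens and counts must have the same length")
  if (anyDuplicated(object@tokens)) return("tokens must be unique")
  if (length(object@counts) && any(object@counts < object@minCount))
    return("all stored counts must be >= minCount")
  TRUE
})

#' Skip-gram embedding model
#'
#' Holds the two dense parameter matrices of a Skip-gram model trained with
#' negative sampling: the input (word) vectors used as embeddings, and the
#' output (context) vectors that parameterize the binary classifiers of the
#' negative-sampling objective. Row i of either matrix belongs to token i of
#' the vocabulary.
#'
#' @slot vocab a [Vocabulary-class].
#' @slot inputVectors numeric matrix, |V| x dim; the embedding looked up for
#'   a center word.
#' @slot outputVectors numeric matrix, |V| x dim; the context-side
#'   parameters.
#' @slot params list of training hyperparameters (see [skipGramParams()]).
#' @export
setClass("SkipGramModel", representation(
  vocab = "Vocabulary",
  inputVectors = "matrix",
  outputVectors = "matrix",
  params = "list"
))

setValidity("SkipGramModel", function(object) {
  nv <- length(object@vocab@tokens)
  if (!identical(dim(object@inputVectors), dim(object@outputVectors)))
    return("input and output matrices must have identical shape")
  if (nrow(object@inputVectors) != nv)
    return("matrix rows must match vocabulary size")
  if (!all(is.finite(object@inputVectors)) ||
      !all(is.finite(object@outputVectors)))
    return("all matrix entries must be finite")
  TRUE
})

#' Per-record feature matrix
#'
#' A block of fixed-length feature vectors for a set of molecules or
#' proteins, under one featurization scheme: summed token embeddings
#' (`smiles2vec`, `protvec`), 166-key MACCS fingerprints (`maccs`) or
#' 20-dimensional amino-acid composition (`aac`).
#'
#' @slot ids character vector of record identifiers (unique).
#' @slot mat numeric matrix, one row per id.
#' @slot scheme one of `"smiles2vec"`, `"protvec"`, `"maccs"`, `"aac"`.
#' @export
setClass("FeatureBlock", representation(
  ids = "character",
  mat = "matrix",
  scheme = "character"
))

setValidity("FeatureBlock", function(object) {
  if (nrow(object@mat) != length(object@ids))
    return("matrix rows must align with ids")
  if (anyDuplicated(object@ids)) return("ids must be unique")
  if (!object@scheme %in% c("smiles2vec", "protvec", "maccs", "aac"))
    return("unknown scheme")
  expected <- c(maccs = 166L, aac = 20L)
  if (object@scheme %in% names(expected) &&
      ncol(object@mat) != expected[[object@scheme]])
    return(sprintf("%s blocks must have %d columns", object@scheme,
                   expected[[object@scheme]]))
  TRUE
})

#' Drug-target pair features
#'
#' Concatenated drug-block and protein-block features for a list of
#' (drug, target) pairs; the row for a pair is
#' `[drug features, protein features]`.
#'
#' @slot drugIds,targetIds character vectors identifying each pair (row).
#' @slot mat numeric matrix with `pDrug + pTarget` columns.
#' @slot combo label for the feature combination, e.g. `"SPVec"` or
#'   `"MACCS-AAC"`.
#' @export
setClass("PairFeatures", representation(
  drugIds = "character",
  targetIds = "character",
  mat = "matrix",
  combo = "character"
))

setValidity("PairFeatures", function(object) {
  n <- nrow(object@mat)
  if (length(object@drugIds) != n || length(object@targetIds) != n)
    return("pair id vectors must align with matrix rows")
  TRUE
})

#' Drug-target interaction dataset
#'
#' Molecules, protein targets and an interaction ledger. Interaction labels
#' are `"positive"`, `"negative"` or `"unlabeled"`; records may carry an
#' IC50 affinity (nM) and a date of first appearance, which drive the
#' affinity filter and the temporal old/new splits.
#'
#' @slot drugs data.frame with columns `id`, `smiles`.
#' @slot targets named [Biostrings::AAStringSet] of protein sequences.
#' @slot interactions data.frame with columns `drug_id`, `target_id`,
#'   `label`, `ic50_nM` (NA allowed), `date_added` (Date, NA allowed).
#' @slot name dataset name.
#' @export
setClass("DTIDataset", representation(
  drugs = "data.frame",
  targets = "AAStringSet",
  interactions = "data.frame",
  name = "character"
))

setValidity("DTIDataset", function(object) {
  need <- c("drug_id", "target_id", "label")
  if (!all(need %in% names(object@interactions)))
    return("interactions needs columns drug_id, target_id, label")
  if (!all(c("id", "smiles") %in% names(object@drugs)))
    return("drugs needs columns id, smiles")
  lab <- object@interactions$label
  if (length(lab) && !all(lab %in% c("positive", "negative", "unlabeled")))
    return("labels must be positive/negative/unlabeled")
  bad <- setdiff(object@interactions$drug_id, object@drugs$id)
  if (length(bad))
    return(sprintf("unresolved drug ids: %s", paste(head(bad, 3), collapse = ", ")))
  bad <- setdiff(object@interactions$target_id, names(object@targets))
  if (length(bad))
    return(sprintf("unresolved target ids: %s", paste(head(bad, 3), collapse = ", ")))
  if ("ic50_nM" %in% names(object@interactions)) {
    v <- object@interactions$ic50_nM
    if (any(!is.na(v) & v <= 0)) return("ic50_nM must be positive when present")
  }
  key <- paste(object@interactions$drug_id, object@interactions$target_id)
  if (any(key[lab == "positive"] %in% key[lab == "negative"]))
    return("a pair cannot be both positive and negative")
  TRUE
})

#' Cross-validation evaluation report
#'
#' Per-(repeat, fold) classification metrics for one feature-combination x
#' classifier cell, with aggregation helpers.
#'
#' @slot folds data.frame with columns `repeat_`, `fold`, `auc`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @slot classifier classifier name (`"gbdt"`, `"rf"`, `"dnn"`).
#' @slot combo feature-combination label.
#' @slot config list: the classifier configuration and CV protocol used.
#' @export
setClass("EvalReport", representation(
  folds = "data.frame",
  classifier = "character",
  combo = "character",
  config = "list"
))

setValidity("EvalReport", function(object) {
  need <- c("repeat_", "fold", "auc", "accuracy", "precision", "recall", "f1")
  if (!all(need %in% names(object@folds)))
    return("folds must carry repeat_, fold and the five metrics")
  m <- as.matrix(object@folds[, c("auc", "accuracy", "precision", "recall", "f1")])
  if (length(m) && (any(m < 0) || any(m > 1)))
    return("all metrics must lie in [0, 1]")
  TRUE
})

#' Low-dimensional projection of an embedding space
#'
#' 2-D or 3-D coordinates for a set of records, optionally carrying a
#' per-point color scalar normalized to [0, 1].
#'
#' @slot ids character vector of record identifiers.
#' @slot coords numeric matrix, n x 2 or n x 3.
#' @slot color numeric vector in [0, 1] (length n) or length 0.
#' @export
setClass("ProjectedCloud", representation(
  ids = "character",
  coords = "matrix",
  color = "numeric"
))

setValidity("ProjectedCloud", function(object) {
  if (nrow(object@coords) != length(object@ids))
    return("coordinate rows must align with ids")
  if (!ncol(object@coords) %in% c(2L, 3L))
    return("coordinates must be 2-D or 3-D")
  if (length(object@color) &&
      (length(object@color) != length(object@ids) ||
       any(object@color < 0 | object@color > 1)))
    return("color must be one value in [0,1] per point")
  TRUE
})
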