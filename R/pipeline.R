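# End-to-end convenience: from a DTI dataset to pair features ready for the
# classifier bench.

#' Train embeddings and build pair features for a DTI dataset
#'
#' Runs the full representation pipeline: tokenizes the dataset's SMILES and
#' protein sequences, trains one Skip-gram model per corpus, sums token
#' vectors into per-record SMILES2Vec / ProtVec blocks, and concatenates them
#' into SPVec pair features for the dataset's interaction ledger (or any
#' supplied pair list).
#'
#' @param dataset a [DTIDataset-class].
#' @param drugParams,proteinParams Skip-gram hyperparameters for the two
#'   corpora (defaults: the standard d = 100, c = 12, k = 15).
#' @param pairs data.frame with `drug_id`, `target_id`; default the dataset's
#'   interactions.
#' @param frameMode protein framing, see [tokenizeProtein()].
#' @param aggregation see [sentenceVector()].
#' @return list with `drugModel`, `proteinModel`, `drugBlock`,
#'   `proteinBlock`, `pairFeatures` and `labels` (0/1, NA for unlabeled
#'   pairs).
#' @export
spvecFeatures <- function(dataset,
                          drugParams = skipGramParams(),
                          proteinParams = skipGramParams(),
                          pairs = NULL,
                          frameMode = c("three_frames", "single"),
                          aggregation = c("sum", "mean")) {
  frameMode <- match.arg(frameMode)
  aggregation <- match.arg(aggregation)
  if (is.null(pairs)) pairs <- dataset@interactions

  drugCorp <- smilesCorpus(dataset@drugs$smiles, dataset@drugs$id)
  protCorp <- proteinCorpus(dataset@targets, frameMode = frameMode)
  drugModel <- trainSkipGram(drugCorp, drugParams)
  proteinModel <- trainSkipGram(protCorp, proteinParams)

  drugBlock <- embedRecords(drugModel,
                            setNames(dataset@drugs$smiles, dataset@drugs$id),
                            kind = "smiles", aggregation = aggregation)
  proteinBlock <- embedRecords(proteinModel, dataset@targets,
                               kind = "protein", aggregation = aggregation,
                               frameMode = frameMode)
  pf <- combineFeatures(drugBlock, proteinBlock, pairs)
  labels <- if ("label" %in% names(pairs))
    ifelse(pairs$label == "positive", 1L,
           ifelse(pairs$label == "negative", 0L, NA_integer_))
  else rep(NA_integer_, nrow(pairs))
  list(drugModel = drugModel, proteinModel = proteinModel,
       drugBlock = drugBlock, proteinBlock = proteinBlock,
       pairFeatures = pf, labels = labels)
}
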