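# Dataset construction: affinity / inorganic / sequence-identity filters,
# seeded negative sampling from the unlabeled pool, and temporal old/new
# splits of a dated interaction ledger.

#' Construct a drug-target interaction dataset
#'
#' @param drugs data.frame with columns `id`, `smiles` (optional `date_added`).
#' @param targets named character vector or [Biostrings::AAStringSet]
#'   (optionally with a `date_added` attribute data.frame, see
#'   [temporalSplit()]).
#' @param interactions data.frame with columns `drug_id`, `target_id`,
#'   `label` and optional `ic50_nM`, `date_added`.
#' @param name dataset name.
#' @return a validated [DTIDataset-class].
#' @export
dtiDataset <- function(drugs, targets, interactions, name = "dataset") {
  if (!is(targets, "AAStringSet"))
    targets <- Biostrings::AAStringSet(targets)
  if (!"ic50_nM" %in% names(interactions))
    interactions$ic50_nM <- rep(NA_real_, nrow(interactions))
  if (!"date_added" %in% names(interactions))
    interactions$date_added <- rep(as.Date(NA), nrow(interactions))
  interactions$date_added <- as.Date(interactions$date_added)
  new("DTIDataset", drugs = drugs, targets = targets,
      interactions = interactions, name = name)
}

#' Filter interactions by binding affinity
#'
#' Keeps interaction records whose IC50 is present and at most `maxIc50nM`;
#' the boundary value is kept (only strictly greater affinities are
#' excluded), and missing affinities are always dropped.
#'
#' @param records data.frame with an `ic50_nM` column.
#' @param maxIc50nM threshold in nM (default 300).
#' @return the surviving rows; a warning is raised when nothing survives.
#' @export
filterByAffinity <- function(records, maxIc50nM = 300) {
  keep <- !is.na(records$ic50_nM) & records$ic50_nM <= maxIc50nM
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no records pass the affinity filter")
  out
}

#' Remove carbon-free (inorganic) molecules
#'
#' A molecule is kept when its tokenized SMILES contains at least one carbon
#' token: `C`, `c`, or a bracket atom whose element is carbon. The tokenizer
#' distinguishes `Cl` from `C`, so chlorinated carbon-free species are
#' removed correctly.
#'
#' @param molecules data.frame with columns `id`, `smiles`.
#' @return the organic subset of rows.
#' @export
filterInorganic <- function(molecules) {
  isOrganic <- vapply(molecules$smiles, function(s) {
    toks <- tokenizeSmiles(s)
    any(toks %in% c("C", "c")) ||
      any(grepl("^\\[[0-9]*[Cc](?![a-z])", toks[startsWith(toks, "[")],
                perl = TRUE))
  }, logical(1))
  molecules[isOrganic, , drop = FALSE]
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment (match +1, mismatch 0, gap opening 10,
#' gap extension 0.5) via Biostrings; identity is the number of identical
#' aligned positions divided by the alignment length.
#'
#' @param a,b amino-acid strings.
#' @return identity in [0, 1].
#' @export
sequenceIdentity <- function(a, b) {
  letters <- unique(c(strsplit(as.character(a), "")[[1]],
                      strsplit(as.character(b), "")[[1]], Biostrings::AA_ALPHABET))
  sm <- matrix(0, length(letters), length(letters),
               dimnames = list(letters, letters))
  diag(sm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(a)), Biostrings::AAString(as.character(b)),
    type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5)
  alnLen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alnLen
}

#' Remove redundant protein targets by sequence identity
#'
#' Greedy longest-first clustering: sequences are visited in order of
#' decreasing length (ties by id) and kept unless their global-alignment
#' identity with an already-kept representative exceeds the threshold; each
#' removed sequence is assigned to the representative that absorbed it.
#'
#' @param sequences named character vector or [Biostrings::AAStringSet].
#' @param identityThreshold identity above which a sequence is considered
#'   redundant (default 0.75, i.e. remove > 75% identity).
#' @return list with `kept` (named character vector of representatives) and
#'   `clusters` (named character vector mapping every input id to its
#'   representative id).
#' @export
filterRedundantTargets <- function(sequences, identityThreshold = 0.75) {
  stopifnot(identityThreshold > 0, identityThreshold < 1)
  nm <- names(sequences)  # base as.character drops names
  seqs <- as.character(sequences)
  ids <- if (!is.null(nm)) nm else as.character(seq_along(seqs))
  names(seqs) <- ids
  ord <- order(-nchar(seqs), ids, method = "radix")
  keptIds <- character(); assign <- character(length(seqs))
  names(assign) <- ids
  for (i in ord) {
    rep_ <- NA_character_
    for (k in keptIds) {
      if (sequenceIdentity(seqs[[i]], seqs[[k]]) > identityThreshold) {
        rep_ <- k; break
      }
    }
    if (is.na(rep_)) {
      keptIds <- c(keptIds, ids[[i]])
      assign[[ids[[i]]]] <- ids[[i]]
    } else {
      assign[[ids[[i]]]] <- rep_
    }
  }
  list(kept = seqs[keptIds], clusters = assign)
}

#' Sample presumed negatives from the unlabeled pool
#'
#' Draws `n` distinct (drug, target) pairs uniformly without replacement from
#' all combinations of the given drugs and targets, excluding the positive
#' set and any extra exclusion set. Reproducible given the seed.
#'
#' @param positives data.frame with columns `drug_id`, `target_id`.
#' @param drugIds,targetIds the id universes spanning the candidate pool.
#' @param n number of negatives to draw.
#' @param seed RNG seed.
#' @param exclusion optional extra data.frame of pairs never to draw.
#' @return data.frame with columns `drug_id`, `target_id` and `label =
#'   "negative"`.
#' @export
sampleNegatives <- function(positives, drugIds, targetIds, n, seed = 1L,
                            exclusion = NULL) {
  drugIds <- unique(as.character(drugIds))
  targetIds <- unique(as.character(targetIds))
  banned <- paste(positives$drug_id, positives$target_id, sep = "\r")
  if (!is.null(exclusion))
    banned <- c(banned, paste(exclusion$drug_id, exclusion$target_id,
                              sep = "\r"))
  # pair p (1-based) maps to drug ((p-1) %% D) + 1, target ((p-1) %/% D) + 1
  allKeys <- paste(rep(drugIds, times = length(targetIds)),
                   rep(targetIds, each = length(drugIds)), sep = "\r")
  pool <- which(!(allKeys %in% banned))
  if (length(pool) < n)
    stop(sprintf("unlabeled pool too small: %d available, %d requested",
                 length(pool), n))
  set.seed(seed)
  pick <- sample(pool, n)
  D <- length(drugIds)
  data.frame(drug_id = drugIds[((pick - 1L) %% D) + 1L],
             target_id = targetIds[((pick - 1L) %/% D) + 1L],
             label = "negative")
}

#' Split a dated interaction ledger into five temporal datasets
#'
#' Entities (drugs, targets) are "old" when their first-appearance date is
#' strictly before the cutoff and "new" otherwise. Interactions are assigned
#' by the age of their endpoints: old drug x old target pairs go to dataset_1
#' when the interaction itself is old and to dataset_2 when it is new;
#' new drug x old target pairs form dataset_3, old drug x new target pairs
#' dataset_4, and new x new pairs dataset_5 — regardless of the interaction
#' date for datasets 3-5. The five interaction sets are disjoint and cover
#' the ledger.
#'
#' @param drugs data.frame with columns `id`, `smiles`, `date_added`.
#' @param targets named character vector / [Biostrings::AAStringSet] of
#'   sequences.
#' @param targetDates data.frame with columns `id`, `date_added`.
#' @param interactions data.frame with `drug_id`, `target_id`, `label`,
#'   `date_added` and optional `ic50_nM`.
#' @param cutoffDate the split date (default `"2016-04-20"`).
#' @return named list of five [DTIDataset-class] objects,
#'   `dataset_1` ... `dataset_5`.
#' @export
temporalSplit <- function(drugs, targets, targetDates, interactions,
                          cutoffDate = as.Date("2016-04-20")) {
  cutoffDate <- as.Date(cutoffDate)
  drugs$date_added <- as.Date(drugs$date_added)
  targetDates$date_added <- as.Date(targetDates$date_added)
  interactions$date_added <- as.Date(interactions$date_added)
  missing <- c(
    if (any(is.na(drugs$date_added)))
      paste("drug", drugs$id[is.na(drugs$date_added)]),
    if (any(is.na(targetDates$date_added)))
      paste("target", targetDates$id[is.na(targetDates$date_added)]),
    if (any(is.na(interactions$date_added)))
      paste("interaction", which(is.na(interactions$date_added))))
  if (length(missing))
    stop("missing dates for: ", paste(missing, collapse = ", "))

  drugOld <- stats::setNames(drugs$date_added < cutoffDate, drugs$id)
  targOld <- stats::setNames(targetDates$date_added < cutoffDate,
                             targetDates$id)
  dOld <- drugOld[interactions$drug_id]
  tOld <- targOld[interactions$target_id]
  iOld <- interactions$date_added < cutoffDate
  bucket <- ifelse(dOld & tOld, ifelse(iOld, 1L, 2L),
            ifelse(!dOld & tOld, 3L, ifelse(dOld & !tOld, 4L, 5L)))

  if (!is(targets, "AAStringSet"))
    targets <- Biostrings::AAStringSet(targets)
  out <- list()
  for (b in 1:5) {
    ints <- interactions[bucket == b, , drop = FALSE]
    dIds <- unique(ints$drug_id); tIds <- unique(ints$target_id)
    out[[paste0("dataset_", b)]] <- dtiDataset(
      drugs[drugs$id %in% dIds, , drop = FALSE],
      targets[names(targets) %in% tIds],
      ints, name = paste0("dataset_", b))
  }
  out
}
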