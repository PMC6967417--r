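# Seeded synthetic data with planted, learnable structure: token corpora
# with co-occurrence classes, protein sequences with planted 3-mer motifs,
# and interaction ledgers whose positives follow latent class matching, with
# affinity values and dates to exercise the filtering and splitting rules.

# Shared SMILES-token alphabet plus disjoint class-specific token sets. All
# tokens are chosen so that concatenation round-trips through the atom-aware
# tokenizer (no token ends where another could start a two-letter atom).
SYNTH_SHARED_TOKENS <- c("C", "c", "O", "N", "(", ")", "=", "1", "2")
SYNTH_CLASS_TOKENS <- list(
  c("S", "Cl", "[NH3+]"),
  c("P", "Br", "[O-]"),
  c("F", "I", "[N+]"),
  c("[Se]", "[Si]", "[B-]")
)

#' Configuration for the synthetic DTI generator
#'
#' Defines a world with `nClasses` latent drug classes matched one-to-one to
#' `nClasses` latent target classes: a (drug, target) pair is truly positive
#' iff their classes match, and observed labels flip with probability
#' `labelNoise`. Drugs are random token strings over a shared SMILES-token
#' alphabet, enriched in their class's disjoint token set; proteins are
#' random sequences with class-specific 3-mer motifs planted at a fixed rate.
#' Positives carry IC50 values at most 300 nM; dates straddle the cutoff so
#' temporal splits are non-trivial.
#'
#' @param nClasses number of latent drug/target classes (default 2).
#' @param drugsPerClass,targetsPerClass records per class (defaults 50, 25).
#' @param smilesLen,seqLen length ranges (tokens / residues) for generated
#'   SMILES and sequences (defaults 20-40 and 120-240).
#' @param classTokenRate probability that a drawn SMILES token comes from the
#'   class-specific set (default 0.5; must be >= 0.3 for the classes to be
#'   learnable).
#' @param motifsPerClass distinct planted 3-mer motifs per target class
#'   (default 3).
#' @param motifRate probability that a 3-mer position carries a class motif
#'   (default 0.12).
#' @param labelNoise label flip probability epsilon in [0, 0.5) (default
#'   0.05).
#' @param cutoffDate date around which entity/interaction dates are drawn.
#' @param seed RNG seed; generation is fully reproducible.
#' @return a validated named list.
#' @export
synthConfig <- function(nClasses = 2L, drugsPerClass = 50L,
                        targetsPerClass = 25L, smilesLen = c(20L, 40L),
                        seqLen = c(120L, 240L), classTokenRate = 0.5,
                        motifsPerClass = 3L, motifRate = 0.12,
                        labelNoise = 0.05,
                        cutoffDate = as.Date("2016-04-20"), seed = 1L) {
  cfg <- list(nClasses = as.integer(nClasses),
              drugsPerClass = as.integer(drugsPerClass),
              targetsPerClass = as.integer(targetsPerClass),
              smilesLen = as.integer(smilesLen), seqLen = as.integer(seqLen),
              classTokenRate = classTokenRate,
              motifsPerClass = as.integer(motifsPerClass),
              motifRate = motifRate, labelNoise = labelNoise,
              cutoffDate = as.Date(cutoffDate), seed = as.integer(seed))
  stopifnot(cfg$nClasses >= 1L, cfg$nClasses <= length(SYNTH_CLASS_TOKENS),
            cfg$drugsPerClass >= 1L, cfg$targetsPerClass >= 1L,
            length(cfg$smilesLen) == 2L, length(cfg$seqLen) == 2L,
            cfg$classTokenRate >= 0.3, cfg$classTokenRate <= 1,
            cfg$motifRate >= 0, cfg$motifRate <= 1,
            cfg$labelNoise >= 0, cfg$labelNoise < 0.5)
  cfg
}

#' Token corpus with planted co-occurrence classes
#'
#' Generates sentences whose tokens are drawn from a shared alphabet mixed
#' with one of several disjoint class-specific token sets; tokens of
#' different classes therefore never co-occur in a sentence beyond the shared
#' alphabet, planting recoverable co-occurrence structure.
#'
#' @param nClasses number of token classes (<= 4).
#' @param sentencesPerClass sentences per class.
#' @param lenRange sentence length range.
#' @param classTokenRate per-token probability of drawing from the class set.
#' @param seed RNG seed.
#' @return a [Corpus-class] of kind `"smiles"` with the class of each
#'   sentence in the `"classes"` attribute.
#' @export
syntheticTokenCorpus <- function(nClasses = 2L, sentencesPerClass = 50L,
                                 lenRange = c(20L, 40L),
                                 classTokenRate = 0.5, seed = 1L) {
  stopifnot(nClasses <= length(SYNTH_CLASS_TOKENS))
  set.seed(seed)
  sentences <- list(); classes <- integer(); ids <- character()
  for (cl in seq_len(nClasses)) {
    for (i in seq_len(sentencesPerClass)) {
      n <- sample(lenRange[1]:lenRange[2], 1)
      fromClass <- runif(n) < classTokenRate
      toks <- ifelse(fromClass,
                     sample(SYNTH_CLASS_TOKENS[[cl]], n, replace = TRUE),
                     sample(SYNTH_SHARED_TOKENS, n, replace = TRUE))
      sentences[[length(sentences) + 1L]] <- toks
      classes <- c(classes, cl)
      ids <- c(ids, sprintf("S%d_%03d", cl, i))
    }
  }
  out <- new("Corpus", sentences = sentences, ids = ids, kind = "smiles")
  attr(out, "classes") <- classes
  out
}

randomSequence <- function(len, motifs, motifRate) {
  nBlocks <- len %/% 3L
  blocks <- character(nBlocks)
  for (b in seq_len(nBlocks)) {
    if (length(motifs) && runif(1) < motifRate)
      blocks[b] <- sample(motifs, 1)
    else
      blocks[b] <- paste(sample(STANDARD_AA, 3, replace = TRUE),
                         collapse = "")
  }
  paste(blocks, collapse = "")
}

#' Generate a synthetic drug-target interaction dataset
#'
#' See [synthConfig()] for the generative model. Every drug x target pair is
#' labeled: truly positive iff latent classes match, then flipped with
#' probability `labelNoise`. Positive pairs draw IC50 log-uniformly in
#' (1, 300] nM; negative pairs either carry an IC50 above 300 nM (30% of
#' them) or none. Entity and interaction dates are uniform over the two
#' years on each side of the cutoff.
#'
#' @param config from [synthConfig()].
#' @return a [DTIDataset-class]; latent classes are attached as attributes
#'   `drugClasses` and `targetClasses` (named integer vectors), and the
#'   per-entity dates as attributes `drugDates` and `targetDates`.
#' @export
generateSynthetic <- function(config = synthConfig()) {
  set.seed(config$seed)
  nc <- config$nClasses

  # drugs: random token strings enriched in the class token set
  drugIds <- character(); drugSmiles <- character(); drugClass <- integer()
  for (cl in seq_len(nc)) {
    for (i in seq_len(config$drugsPerClass)) {
      n <- sample(config$smilesLen[1]:config$smilesLen[2], 1)
      fromClass <- runif(n) < config$classTokenRate
      toks <- ifelse(fromClass,
                     sample(SYNTH_CLASS_TOKENS[[cl]], n, replace = TRUE),
                     sample(SYNTH_SHARED_TOKENS, n, replace = TRUE))
      drugIds <- c(drugIds, sprintf("D%d_%03d", cl, i))
      drugSmiles <- c(drugSmiles, paste(toks, collapse = ""))
      drugClass <- c(drugClass, cl)
    }
  }

  # targets: random sequences with class motifs planted at motifRate
  motifs <- lapply(seq_len(nc), function(cl)
    vapply(seq_len(config$motifsPerClass), function(m)
      paste(sample(STANDARD_AA, 3, replace = TRUE), collapse = ""),
      character(1)))
  targetIds <- character(); targetSeqs <- character(); targetClass <- integer()
  for (cl in seq_len(nc)) {
    for (i in seq_len(config$targetsPerClass)) {
      len <- sample(config$seqLen[1]:config$seqLen[2], 1)
      targetIds <- c(targetIds, sprintf("T%d_%03d", cl, i))
      targetSeqs <- c(targetSeqs,
                      randomSequence(len, motifs[[cl]], config$motifRate))
      targetClass <- c(targetClass, cl)
    }
  }

  # full interaction ledger over all pairs
  grid <- expand.grid(d = seq_along(drugIds), t = seq_along(targetIds))
  truth <- drugClass[grid$d] == targetClass[grid$t]
  flip <- runif(nrow(grid)) < config$labelNoise
  positive <- xor(truth, flip)
  ic50 <- rep(NA_real_, nrow(grid))
  ic50[positive] <- 10^runif(sum(positive), 0, log10(300))
  hasHigh <- !positive & runif(nrow(grid)) < 0.3
  ic50[hasHigh] <- runif(sum(hasHigh), 301, 10000)

  span <- 2 * 365
  drugDates <- config$cutoffDate + sample(-span:span, length(drugIds), TRUE)
  targetDates <- config$cutoffDate + sample(-span:span, length(targetIds), TRUE)
  pairDates <- config$cutoffDate + sample(-span:span, nrow(grid), TRUE)
  # an interaction can be recorded no earlier than either endpoint
  pairDates <- pmax(pairDates, drugDates[grid$d], targetDates[grid$t])

  interactions <- data.frame(
    drug_id = drugIds[grid$d], target_id = targetIds[grid$t],
    label = ifelse(positive, "positive", "negative"),
    ic50_nM = ic50, date_added = pairDates)

  ds <- dtiDataset(
    drugs = data.frame(id = drugIds, smiles = drugSmiles,
                       date_added = drugDates),
    targets = stats::setNames(targetSeqs, targetIds),
    interactions = interactions, name = "synthetic")
  attr(ds, "drugClasses") <- stats::setNames(drugClass, drugIds)
  attr(ds, "targetClasses") <- stats::setNames(targetClass, targetIds)
  attr(ds, "drugDates") <- stats::setNames(drugDates, drugIds)
  attr(ds, "targetDates") <- stats::setNames(targetDates, targetIds)
  ds
}
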