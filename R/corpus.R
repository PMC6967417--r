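# Tokenization of SMILES strings and protein sequences into the "sentences"
# and "words" over which Skip-gram embeddings are trained.

#' Tokenize a SMILES string into an atom-aware sentence
#'
#' Splits a SMILES string left-to-right into tokens such that concatenating
#' the tokens reproduces the input exactly: bracket atoms (`[...]`) and the
#' two-letter organic-subset halogens `Cl`/`Br` are single tokens; every other
#' character (atoms, bonds, ring digits, branch parentheses, dots) is its own
#' token. With `mode = "char"` every character is a token, brackets included.
#'
#' @param smiles a single non-empty SMILES string.
#' @param mode `"atom"` (default, atom-aware) or `"char"` (pure
#'   per-character).
#' @return character vector of tokens.
#' @examples
#' tokenizeSmiles("c1ccccc1Br")
#' tokenizeSmiles("[NH4+]")
#' @export
tokenizeSmiles <- function(smiles, mode = c("atom", "char")) {
  mode <- match.arg(mode)
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    stop("smiles must be a single non-empty string")
  if (mode == "char") {
    toks <- strsplit(smiles, "", fixed = TRUE)[[1]]
    if (!bracketsBalanced(smiles))
      stop(sprintf("malformed SMILES (unclosed bracket): %s", smiles))
    return(toks)
  }
  toks <- regmatches(smiles,
                     gregexpr("\\[[^][]*\\]|Cl|Br|.", smiles))[[1]]
  if (any(toks %in% c("[", "]")))
    stop(sprintf("malformed SMILES (unclosed bracket): %s", smiles))
  toks
}

bracketsBalanced <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (ch in chars) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (depth < 0L || depth > 1L) return(FALSE)
  }
  depth == 0L
}

#' Tokenize a protein sequence into 3-mer word sentences
#'
#' Decomposes an amino-acid sequence into non-overlapping 3-mer "words". In
#' `"single"` mode one sentence is produced, starting at the first residue;
#' in `"three_frames"` mode the three reading frames (offsets 0, 1, 2) each
#' yield a sentence. Trailing residues shorter than a full 3-mer are dropped,
#' and frames left empty by that rule are omitted. Nonstandard residue
#' letters are kept verbatim inside their 3-mers.
#'
#' @param sequence a single amino-acid string (or an
#'   [Biostrings::AAString]-coercible object).
#' @param frameMode `"three_frames"` (default) or `"single"`.
#' @return list of character vectors (sentences); empty with a warning when
#'   the sequence is shorter than 3 residues.
#' @examples
#' tokenizeProtein("MKVLAG", "single")
#' tokenizeProtein("MKVLAG", "three_frames")
#' @export
tokenizeProtein <- function(sequence, frameMode = c("three_frames", "single")) {
  frameMode <- match.arg(frameMode)
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single string")
  L <- nchar(sequence)
  if (L < 3L) {
    warning("sequence shorter than 3 residues yields no 3-mer words")
    return(list())
  }
  offsets <- if (frameMode == "single") 0L else 0:2
  out <- list()
  for (f in offsets) {
    n <- (L - f) %/% 3L
    if (n < 1L) next
    starts <- f + 1L + 3L * (seq_len(n) - 1L)
    out[[length(out) + 1L]] <- substring(sequence, starts, starts + 2L)
  }
  out
}

#' Build a corpus from SMILES records
#'
#' @param smiles character vector of SMILES strings.
#' @param ids record identifiers (defaults to names or positions).
#' @param mode tokenization mode, see [tokenizeSmiles()].
#' @return a [Corpus-class] of kind `"smiles"` with one sentence per record.
#' @export
smilesCorpus <- function(smiles, ids = NULL, mode = c("atom", "char")) {
  mode <- match.arg(mode)
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  stopifnot(length(ids) == length(smiles))
  new("Corpus",
      sentences = unname(lapply(smiles, tokenizeSmiles, mode = mode)),
      ids = as.character(ids), kind = "smiles")
}

#' Build a corpus from protein sequences
#'
#' @param sequences character vector or [Biostrings::AAStringSet].
#' @param ids record identifiers (defaults to names).
#' @param frameMode see [tokenizeProtein()].
#' @return a [Corpus-class] of kind `"protein"`; a record contributes one
#'   sentence per non-empty reading frame.
#' @export
proteinCorpus <- function(sequences, ids = NULL,
                          frameMode = c("three_frames", "single")) {
  frameMode <- match.arg(frameMode)
  nm <- names(sequences)  # base as.character drops names
  seqs <- as.character(sequences)
  if (is.null(ids)) ids <- if (!is.null(nm)) nm else
    as.character(seq_along(seqs))
  stopifnot(length(ids) == length(seqs))
  sent <- list(); sid <- character()
  for (i in seq_along(seqs)) {
    frames <- tokenizeProtein(seqs[[i]], frameMode)
    sent <- c(sent, frames)
    sid <- c(sid, rep(ids[[i]], length(frames)))
  }
  new("Corpus", sentences = sent, ids = sid, kind = "protein")
}

#' Build a token vocabulary from a corpus
#'
#' Counts token occurrences over all sentences, drops tokens occurring fewer
#' than `minCount` times, and fixes a deterministic index order: descending
#' count, ties broken lexicographically.
#'
#' @param corpus a [Corpus-class].
#' @param minCount minimum occurrence count to keep a token (default 1).
#' @return a [Vocabulary-class].
#' @export
buildVocab <- function(corpus, minCount = 1L) {
  stopifnot(is(corpus, "Corpus"))
  if (length(corpus@sentences) == 0L) stop("corpus is empty")
  tab <- table(unlist(corpus@sentences, use.names = FALSE))
  counts <- as.integer(tab)
  tokens <- names(tab)
  keep <- counts >= minCount
  if (!any(keep)) stop("vocabulary is empty after min_count filtering")
  tokens <- tokens[keep]; counts <- counts[keep]
  ord <- order(-counts, tokens, method = "radix")
  new("Vocabulary", tokens = tokens[ord], counts = counts[ord],
      minCount = as.integer(minCount))
}

#' Enumerate (center, context) training pairs of a sentence
#'
#' For each position i, emits one ordered pair per position j with
#' `0 < |i - j| <= window`. The window is fixed and symmetric (no random
#' shrinking), so the emitted pair set is symmetric: (a, b) appears iff
#' (b, a) does.
#'
#' @param sentence character vector of tokens.
#' @param window context half-width c (>= 1).
#' @return data.frame with character columns `center`, `context`; zero rows
#'   for sentences of fewer than two tokens.
#' @export
contextPairs <- function(sentence, window) {
  stopifnot(window >= 1)
  n <- length(sentence)
  if (n < 2L)
    return(data.frame(center = character(), context = character()))
  ci <- integer(); cj <- integer()
  for (i in seq_len(n)) {
    j <- setdiff(max(1L, i - window):min(n, i + window), i)
    ci <- c(ci, rep.int(i, length(j)))
    cj <- c(cj, j)
  }
  data.frame(center = sentence[ci], context = sentence[cj])
}
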