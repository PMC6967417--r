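# Fixed-length feature vectors: summed token embeddings (SMILES2Vec /
# ProtVec), MACCS fingerprints, amino-acid composition, and per-residue
# physicochemical profiles.

STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Embed one record's sentence(s) as a single vector
#'
#' Sums (default) or averages the input vectors of a record's tokens over all
#' of its sentences — for proteins in three-frame mode that is the sum over
#' all frames' 3-mers. Out-of-vocabulary tokens are skipped and counted; a
#' record whose tokens are all out-of-vocabulary yields the zero vector and
#' is flagged.
#'
#' @param model a [SkipGramModel-class].
#' @param sentences a single character vector of tokens, or a list of them.
#' @param aggregation `"sum"` (default) or `"mean"` over in-vocabulary
#'   tokens.
#' @return numeric vector of length `dim`, with attributes `oov` (number of
#'   skipped tokens) and `allOov` (logical flag).
#' @export
sentenceVector <- function(model, sentences, aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  if (!is.list(sentences)) sentences <- list(sentences)
  tokens <- unlist(sentences, use.names = FALSE)
  idx <- match(tokens, model@vocab@tokens)
  oov <- sum(is.na(idx))
  idx <- idx[!is.na(idx)]
  p <- ncol(model@inputVectors)
  if (length(idx) == 0L) {
    v <- numeric(p)
    attr(v, "oov") <- oov; attr(v, "allOov") <- TRUE
    return(v)
  }
  v <- colSums(model@inputVectors[idx, , drop = FALSE])
  if (aggregation == "mean") v <- v / length(idx)
  attr(v, "oov") <- oov; attr(v, "allOov") <- FALSE
  v
}

#' Embed a set of records into a feature block
#'
#' Applies [sentenceVector()] to each record of a SMILES or protein input and
#' stacks the results. Records flagged all-out-of-vocabulary are reported via
#' the `"flagged"` attribute; the total skipped-token count is logged as a
#' message.
#'
#' @param model a [SkipGramModel-class].
#' @param x named character vector of SMILES strings (kind `"smiles"`) or
#'   sequences / [Biostrings::AAStringSet] (kind `"protein"`).
#' @param kind `"smiles"` or `"protein"`.
#' @param ids record identifiers; default names of `x`.
#' @param aggregation see [sentenceVector()].
#' @param frameMode protein framing, see [tokenizeProtein()].
#' @param mode SMILES tokenization mode, see [tokenizeSmiles()].
#' @return a [FeatureBlock-class] of scheme `"smiles2vec"` or `"protvec"`.
#' @export
embedRecords <- function(model, x, kind = c("smiles", "protein"), ids = NULL,
                         aggregation = c("sum", "mean"),
                         frameMode = c("three_frames", "single"),
                         mode = c("atom", "char")) {
  kind <- match.arg(kind); aggregation <- match.arg(aggregation)
  frameMode <- match.arg(frameMode); mode <- match.arg(mode)
  xs <- as.character(x)
  if (is.null(ids)) ids <- if (!is.null(names(x))) names(x) else
    as.character(seq_along(xs))
  if (length(xs) == 0L) stop("no records to embed")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  p <- ncol(model@inputVectors)
  mat <- matrix(0, nrow = length(xs), ncol = p)
  flagged <- character(); oovTotal <- 0L
  for (i in seq_along(xs)) {
    sent <- if (kind == "smiles") list(tokenizeSmiles(xs[[i]], mode)) else
      tokenizeProtein(xs[[i]], frameMode)
    v <- sentenceVector(model, sent, aggregation)
    mat[i, ] <- v
    oovTotal <- oovTotal + attr(v, "oov")
    if (isTRUE(attr(v, "allOov"))) flagged <- c(flagged, ids[[i]])
  }
  if (oovTotal > 0L)
    message(sprintf("embedRecords: skipped %d out-of-vocabulary token(s); %d record(s) all-OOV",
                    oovTotal, length(flagged)))
  out <- new("FeatureBlock", ids = as.character(ids), mat = mat,
             scheme = if (kind == "smiles") "smiles2vec" else "protvec")
  attr(out, "flagged") <- flagged
  out
}

#' Amino-acid composition descriptor
#'
#' The 20-vector of relative frequencies of the standard amino acids,
#' computed over the sequence's standard residues only (nonstandard letters
#' are excluded from numerator and denominator); components sum to 1.
#'
#' @param sequence a single amino-acid string.
#' @return named numeric vector of length 20 in standard residue order.
#' @examples
#' aac("ACDEFGHIKLMNPQRSTVWY")
#' @export
aac <- function(sequence) {
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || !nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% STANDARD_AA]
  if (length(chars) == 0L) stop("sequence contains no standard residues")
  counts <- table(factor(chars, levels = STANDARD_AA))
  v <- as.numeric(counts) / length(chars)
  names(v) <- STANDARD_AA
  v
}

#' AAC feature block for a set of proteins
#'
#' @param sequences named character vector or [Biostrings::AAStringSet].
#' @param ids identifiers; default names.
#' @return a [FeatureBlock-class] of scheme `"aac"` (20 columns).
#' @export
aacBlock <- function(sequences, ids = NULL) {
  nm <- names(sequences)  # base as.character drops names
  seqs <- as.character(sequences)
  if (is.null(ids)) ids <- if (!is.null(nm)) nm else
    as.character(seq_along(seqs))
  mat <- t(vapply(seqs, aac, numeric(20)))
  dimnames(mat) <- NULL
  new("FeatureBlock", ids = as.character(ids), mat = mat, scheme = "aac")
}

#' MACCS structural-key fingerprint
#'
#' The 166 public MACCS substructure keys as a binary vector, computed with
#' the OpenBabel SMARTS implementation via ChemmineOB (whose key numbering
#' matches the standard 166-key set; the padded bits beyond key 166 are
#' dropped).
#'
#' @param smiles character vector of SMILES strings.
#' @param ids identifiers; default names.
#' @return a [FeatureBlock-class] of scheme `"maccs"` (166 binary columns).
#' @export
maccsBlock <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    as.character(seq_along(smiles))
  smiles <- as.character(smiles)
  bad <- !vapply(smiles, smilesParseable, logical(1))
  if (any(bad))
    stop("unparseable SMILES for record(s): ",
         paste(ids[bad], collapse = ", "))
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, ids))
  fp <- ChemmineR::fingerprintOB(sdf, "MACCS")
  mat <- fp@fpma[, 1:166, drop = FALSE]
  dimnames(mat) <- NULL
  mode(mat) <- "numeric"
  new("FeatureBlock", ids = as.character(ids), mat = mat, scheme = "maccs")
}

#' @rdname maccsBlock
#' @export
maccs <- function(smiles) {
  as.numeric(maccsBlock(smiles[1])@mat[1, ])
}

# A SMILES is considered parseable when OpenBabel reads at least one atom
# from it without error.
smilesParseable <- function(s) {
  if (!nzchar(s) || !bracketsBalanced(s)) return(FALSE)
  ok <- TRUE
  tryCatch({
    suppressWarnings({
      out <- utils::capture.output(
        sdf <- ChemmineR::smiles2sdf(s), type = "message")
      ab <- ChemmineR::atomblock(sdf[[1]])
    })
    if (is.null(ab) || nrow(ab) == 0L) ok <- FALSE
  }, error = function(e) ok <<- FALSE)
  ok
}

#' Concatenate drug and protein features into pair features
#'
#' Builds the row `[drug features, protein features]` for each (drug, target)
#' pair; with the default 100-dimensional embeddings, SPVec rows have 200
#' columns, and the MACCS-AAC baseline 186.
#'
#' @param drugBlock,proteinBlock [FeatureBlock-class] objects.
#' @param pairs data.frame with columns `drug_id`, `target_id`.
#' @param combo label for the combination; by default derived from the two
#'   schemes (`"SPVec"` for smiles2vec + protvec).
#' @return a [PairFeatures-class].
#' @export
combineFeatures <- function(drugBlock, proteinBlock, pairs, combo = NULL) {
  stopifnot(is(drugBlock, "FeatureBlock"), is(proteinBlock, "FeatureBlock"))
  di <- match(pairs$drug_id, drugBlock@ids)
  ti <- match(pairs$target_id, proteinBlock@ids)
  if (anyNA(di))
    stop("unknown drug ids: ",
         paste(unique(pairs$drug_id[is.na(di)]), collapse = ", "))
  if (anyNA(ti))
    stop("unknown target ids: ",
         paste(unique(pairs$target_id[is.na(ti)]), collapse = ", "))
  if (is.null(combo)) {
    key <- paste(drugBlock@scheme, proteinBlock@scheme, sep = "-")
    combo <- c("smiles2vec-protvec" = "SPVec",
               "smiles2vec-aac" = "SMILES2Vec-AAC",
               "maccs-protvec" = "MACCS-ProtVec",
               "maccs-aac" = "MACCS-AAC")[key]
    if (is.na(combo)) combo <- key
  }
  mat <- cbind(drugBlock@mat[di, , drop = FALSE],
               proteinBlock@mat[ti, , drop = FALSE])
  new("PairFeatures", drugIds = as.character(pairs$drug_id),
      targetIds = as.character(pairs$target_id), mat = mat,
      combo = unname(combo))
}

#' Per-residue physicochemical scales
#'
#' Four standard per-residue scales used to color embedding projections:
#' monoisotopic residue masses (Da), Zamyatnin side-chain volumes (cubic
#' Angstrom), Grantham polarity, and Kyte-Doolittle hydropathy.
#'
#' @return data.frame with row names the 20 standard residues and columns
#'   `mass`, `volume`, `polarity`, `hydrophobicity`.
#' @export
aminoAcidScales <- function() {
  data.frame(
    mass = c(A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
             F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
             K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
             P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
             T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333),
    volume = c(A = 88.6, C = 108.5, D = 111.1, E = 138.4, F = 189.9,
               G = 60.1, H = 153.2, I = 166.7, K = 168.6, L = 166.7,
               M = 162.9, N = 114.1, P = 112.7, Q = 143.8, R = 173.4,
               S = 89.0, T = 116.1, V = 140.0, W = 227.8, Y = 193.6),
    polarity = c(A = 8.1, C = 5.5, D = 13.0, E = 12.3, F = 5.2, G = 9.0,
                 H = 10.4, I = 5.2, K = 11.3, L = 4.9, M = 5.7, N = 11.6,
                 P = 8.0, Q = 10.5, R = 10.5, S = 9.2, T = 8.6, V = 5.9,
                 W = 5.4, Y = 6.2),
    hydrophobicity = c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8,
                       G = -0.4, H = -3.2, I = 4.5, K = -3.9, L = 3.8,
                       M = 1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
                       S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
  )
}

#' Mean physicochemical profile of a protein
#'
#' Averages each per-residue scale of [aminoAcidScales()] over the sequence's
#' standard residues (nonstandard letters are ignored).
#'
#' @param sequence a single amino-acid string with at least one standard
#'   residue.
#' @return named numeric vector `mass`, `volume`, `polarity`,
#'   `hydrophobicity`.
#' @export
propertyProfile <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% STANDARD_AA]
  if (length(chars) == 0L) stop("sequence contains no standard residues")
  scales <- aminoAcidScales()
  vapply(scales, function(col) mean(col[match(chars, rownames(scales))]),
         numeric(1))
}
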