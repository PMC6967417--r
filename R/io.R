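# Flat-file I/O: .smi molecule lists, FASTA proteins, interaction TSVs,
# tokenized-corpus text, the word2vec text format for embeddings, and
# dataset directories combining the three record files.

#' Read a .smi molecule file
#'
#' One record per line: a SMILES string, optionally followed by a
#' whitespace-separated identifier. Records without an identifier are
#' numbered by position.
#'
#' @param path file path.
#' @return data.frame with columns `id`, `smiles`.
#' @export
readSmi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[ \t]+")
  data.frame(
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][2] else as.character(i),
      character(1)),
    smiles = vapply(parts, `[`, character(1), 1))
}

#' Write a .smi molecule file
#'
#' @param molecules data.frame with columns `id`, `smiles`.
#' @param path file path.
#' @export
writeSmi <- function(molecules, path) {
  writeLines(paste(molecules$smiles, molecules$id), path)
}

#' Read protein sequences from FASTA
#'
#' @param path file path.
#' @return a named [Biostrings::AAStringSet]; names are the first
#'   whitespace-separated word of each header.
#' @export
readFastaProteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "[ \t]"), `[`, character(1), 1)
  seqs
}

#' Read an interaction ledger TSV
#'
#' Expects a header with columns `drug_id`, `target_id`, `label` and
#' optionally `ic50_nM`, `date_added`; empty fields are missing values.
#'
#' @param path file path.
#' @return data.frame with typed columns (`ic50_nM` numeric, `date_added`
#'   Date).
#' @export
readInteractions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  need <- c("drug_id", "target_id", "label")
  if (!all(need %in% names(df)))
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  if (!"ic50_nM" %in% names(df)) df$ic50_nM <- NA_real_
  df$ic50_nM <- as.numeric(df$ic50_nM)
  if (!"date_added" %in% names(df)) df$date_added <- NA
  df$date_added <- as.Date(df$date_added)
  df
}

#' @rdname readInteractions
#' @param interactions data.frame to write.
#' @export
writeInteractions <- function(interactions, path) {
  write.table(interactions, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
}

#' Write and read a tokenized corpus as plain text
#'
#' One sentence per line, tokens space-separated; sentence ids are stored in
#' a sidecar `.ids` file next to the corpus.
#'
#' @param corpus a [Corpus-class].
#' @param path file path.
#' @export
writeCorpusText <- function(corpus, path) {
  writeLines(vapply(corpus@sentences, paste, character(1), collapse = " "),
             path)
  writeLines(c(corpus@kind, corpus@ids), paste0(path, ".ids"))
}

#' @rdname writeCorpusText
#' @return `readCorpusText` returns the [Corpus-class].
#' @export
readCorpusText <- function(path) {
  sentences <- strsplit(readLines(path, warn = FALSE), " ", fixed = TRUE)
  meta <- readLines(paste0(path, ".ids"), warn = FALSE)
  new("Corpus", sentences = sentences, ids = meta[-1], kind = meta[1])
}

#' Persist a Skip-gram model in word2vec text format
#'
#' Writes `<prefix>.vectors.txt` (input vectors; header line
#' `"<vocab_size> <dim>"`, then one line per token), a sidecar
#' `<prefix>.output.txt` with the output vectors in the same layout, and
#' `<prefix>.meta.json` carrying the hyperparameters and vocabulary counts.
#'
#' @param model a [SkipGramModel-class].
#' @param prefix path prefix for the three files.
#' @export
writeEmbeddings <- function(model, prefix) {
  writeW2vMatrix <- function(mat, tokens, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con)
    writeLines(paste(tokens,
                     apply(mat, 1, function(r)
                       paste(format(r, digits = 17, scientific = TRUE,
                                    trim = TRUE), collapse = " "))), con)
  }
  toks <- model@vocab@tokens
  writeW2vMatrix(model@inputVectors, toks, paste0(prefix, ".vectors.txt"))
  writeW2vMatrix(model@outputVectors, toks, paste0(prefix, ".output.txt"))
  jsonlite::write_json(
    list(params = model@params, counts = as.list(vocabCounts(model@vocab)),
         minCount = model@vocab@minCount),
    paste0(prefix, ".meta.json"), auto_unbox = TRUE, digits = NA)
}

#' @rdname writeEmbeddings
#' @return `readEmbeddings` returns the reconstructed
#'   [SkipGramModel-class].
#' @export
readEmbeddings <- function(prefix) {
  readW2vMatrix <- function(path) {
    lines <- readLines(path, warn = FALSE)
    hdr <- as.integer(strsplit(lines[1], " ")[[1]])
    parts <- strsplit(lines[-1], " ", fixed = TRUE)
    tokens <- vapply(parts, `[`, character(1), 1)
    mat <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
    list(tokens = tokens, mat = mat)
  }
  vin <- readW2vMatrix(paste0(prefix, ".vectors.txt"))
  vout <- readW2vMatrix(paste0(prefix, ".output.txt"))
  meta <- jsonlite::read_json(paste0(prefix, ".meta.json"),
                              simplifyVector = TRUE)
  vocab <- new("Vocabulary", tokens = vin$tokens,
               counts = as.numeric(meta$counts[vin$tokens]),
               minCount = as.integer(meta$minCount))
  new("SkipGramModel", vocab = vocab, inputVectors = vin$mat,
      outputVectors = vout$mat, params = as.list(meta$params))
}

#' Persist a feature block as TSV
#'
#' An `id` column followed by numbered feature columns (`f1`, `f2`, ...).
#'
#' @param block a [FeatureBlock-class].
#' @param path file path.
#' @export
writeFeatureBlock <- function(block, path) {
  df <- data.frame(id = block@ids, block@mat)
  colnames(df) <- c("id", paste0("f", seq_len(ncol(block@mat))))
  attr(df, "scheme") <- block@scheme
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a DTI dataset as a directory of flat files
#'
#' Produces `drugs.smi`, `targets.fasta` and `interactions.tsv` under `dir`.
#'
#' @param dataset a [DTIDataset-class].
#' @param dir output directory (created if needed).
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeSmi(dataset@drugs, file.path(dir, "drugs.smi"))
  Biostrings::writeXStringSet(dataset@targets,
                              file.path(dir, "targets.fasta"))
  writeInteractions(dataset@interactions, file.path(dir, "interactions.tsv"))
}

#' @rdname writeDataset
#' @param name dataset name for the reconstructed object.
#' @return `readDataset` returns the [DTIDataset-class].
#' @export
readDataset <- function(dir, name = basename(dir)) {
  dtiDataset(readSmi(file.path(dir, "drugs.smi")),
             readFastaProteins(file.path(dir, "targets.fasta")),
             readInteractions(file.path(dir, "interactions.tsv")),
             name = name)
}

#' Persist an evaluation report
#'
#' Writes the full per-fold records as JSON and a one-row TSV summary
#' (combo, classifier, then the mean of each metric over all folds).
#'
#' @param report an [EvalReport-class].
#' @param prefix path prefix; writes `<prefix>.json` and
#'   `<prefix>.summary.tsv`.
#' @export
writeEvalReport <- function(report, prefix) {
  jsonlite::write_json(
    list(combo = report@combo, classifier = report@classifier,
         config = report@config, folds = report@folds),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  agg <- aggregateMetrics(report)
  row <- data.frame(combo = report@combo, classifier = report@classifier,
                    t(setNames(agg$mean, agg$metric)))
  colnames(row) <- c("combo", "classifier", "AUC", "Accuracy", "Precision",
                     "Recall", "F1-score")
  write.table(row, paste0(prefix, ".summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
}
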