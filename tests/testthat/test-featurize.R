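mkModel <- function(tokens, dim = 4, seed = 2) {
  set.seed(seed)
  vocab <- new("Vocabulary", tokens = tokens,
               counts = rep(2, length(tokens)), minCount = 1L)
  new("SkipGramModel", vocab = vocab,
      inputVectors = matrix(rnorm(length(tokens) * dim), ncol = dim),
      outputVectors = matrix(rnorm(length(tokens) * dim), ncol = dim),
      params = skipGramParams(dim = dim))
}

test_that("sentence vectors sum token embeddings and flag OOV input", {
  m <- mkModel(c("C", "O", "N"))
  v <- sentenceVector(m, c("C", "C"))
  expect_equal(as.numeric(v), 2 * m@inputVectors[1, ])
  expect_equal(attr(v, "oov"), 0)
  allOov <- sentenceVector(m, c("Z", "Q"))
  expect_equal(as.numeric(allOov), rep(0, 4))
  expect_true(attr(allOov, "allOov"))
  expect_equal(attr(allOov, "oov"), 2)
  # brute-force accumulation on a random sentence, and mean aggregation
  set.seed(9)
  s <- sample(c("C", "O", "N", "Z"), 12, replace = TRUE)
  expected <- rep(0, 4); nIn <- 0
  for (t in s) {
    i <- match(t, c("C", "O", "N"))
    if (!is.na(i)) { expected <- expected + m@inputVectors[i, ]; nIn <- nIn + 1 }
  }
  expect_equal(as.numeric(sentenceVector(m, s)), expected)
  expect_equal(as.numeric(sentenceVector(m, s, "mean")), expected / nIn)
})

test_that("sum aggregation is additive over concatenated sentences", {
  m <- mkModel(c("C", "O", "N", "S"))
  s1 <- c("C", "O", "S"); s2 <- c("N", "N", "C")
  expect_equal(as.numeric(sentenceVector(m, list(s1, s2))),
               as.numeric(sentenceVector(m, s1)) +
                 as.numeric(sentenceVector(m, s2)))
})

test_that("embedRecords builds aligned blocks and rejects duplicate ids", {
  m <- mkModel(c("C", "O", "N", "c", "1"))
  sm <- c(a = "CCO", b = "c1cc1", d = "NNO")
  blk <- embedRecords(m, sm, "smiles")
  expect_s4_class(blk, "FeatureBlock")
  expect_equal(dim(featureMatrix(blk)), c(3, 4))
  expect_identical(featureIds(blk), c("a", "b", "d"))
  # permuting input order permutes rows identically
  blk2 <- embedRecords(m, sm[c(3, 1, 2)], "smiles")
  expect_equal(featureMatrix(blk2)[c("a", "b", "d"), ],
               featureMatrix(blk)[c("a", "b", "d"), ])
  expect_error(embedRecords(m, c(a = "CC", a = "CO"), "smiles"), "duplicate")
  expect_error(embedRecords(m, character(0), "smiles"), "no records")
})

test_that("amino-acid composition is a normalized 20-vector", {
  v <- aac("AAAA")
  expect_length(v, 20)
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(aac("ACDEFGHIKLMNPQRSTVWY")), rep(0.05, 20))
  # nonstandard residues excluded from numerator and denominator
  expect_equal(unname(aac("AX")["A"]), 1)
  expect_error(aac("XXX"), "standard")
  # normalization property on random sequences
  set.seed(4)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "W", "Y", "X", "B"), 30, replace = TRUE),
               collapse = "")
    v <- aac(s)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0 & v <= 1))
  }
  blk <- aacBlock(c(p1 = "AAAA", p2 = "ACWY"))
  expect_equal(dim(featureMatrix(blk)), c(2, 20))
})

test_that("MACCS fingerprints are 166 binary keys and fail loudly", {
  v <- maccs("CCO")
  expect_length(v, 166)
  expect_true(all(v %in% c(0, 1)))
  blk <- maccsBlock(c(eth = "CCO", benz = "c1ccccc1"))
  expect_equal(ncol(featureMatrix(blk)), 166)
  # ethanol sets the alcohol-related keys, benzene the aromatic-ring ones
  expect_true(any(featureMatrix(blk)["eth", ] !=
                    featureMatrix(blk)["benz", ]))
  expect_error(maccsBlock(c(ok = "CCO", bad = "not_a_smiles")), "bad")
})

test_that("pair features concatenate drug and protein blocks", {
  db <- new("FeatureBlock", ids = c("d1", "d2"),
            mat = matrix(1:6, 2, 3), scheme = "smiles2vec")
  pb <- new("FeatureBlock", ids = c("t1", "t2"),
            mat = matrix(7:10, 2, 2), scheme = "protvec")
  pairs <- data.frame(drug_id = c("d1", "d2"), target_id = c("t2", "t1"))
  pf <- combineFeatures(db, pb, pairs)
  expect_equal(ncol(featureMatrix(pf)), 5)
  expect_equal(featureMatrix(pf)[1, ], c(db@mat[1, ], pb@mat[2, ]))
  expect_equal(pf@combo, "SPVec")
  expect_error(combineFeatures(db, pb,
                               data.frame(drug_id = "nope", target_id = "t1")),
               "unknown drug")
  # MACCS + AAC gives the classical 186 columns
  dbM <- maccsBlock(c(d1 = "CCO"))
  pbA <- aacBlock(c(t1 = "ACDEFG"))
  pfM <- combineFeatures(dbM, pbA,
                         data.frame(drug_id = "d1", target_id = "t1"))
  expect_equal(ncol(featureMatrix(pfM)), 186)
  expect_equal(pfM@combo, "MACCS-AAC")
})

test_that("property profiles are per-residue scale means", {
  scales <- aminoAcidScales()
  g <- propertyProfile("GGGG")
  expect_equal(unname(g), unlist(scales["G", ]), ignore_attr = TRUE)
  # mean composition rule
  expect_equal(propertyProfile("AG"),
               (propertyProfile("A") + propertyProfile("G")) / 2)
  # random sequence vs independent recomputation from the shipped table
  set.seed(12)
  s <- paste(sample(rownames(scales), 40, replace = TRUE), collapse = "")
  chars <- strsplit(s, "")[[1]]
  for (p in colnames(scales))
    expect_equal(unname(propertyProfile(s)[p]),
                 mean(scales[chars, p]))
  expect_error(propertyProfile("XZB"), "standard")
})
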