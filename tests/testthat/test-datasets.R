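toyLedger <- function() {
  data.frame(drug_id = paste0("d", 1:4), target_id = paste0("t", 1:4),
             label = "positive", ic50_nM = c(250, 300, 301, NA),
             date_added = as.Date("2015-01-01"))
}

test_that("affinity filter keeps <= 300 nM, drops missing, is idempotent", {
  led <- toyLedger()
  kept <- filterByAffinity(led)
  expect_equal(nrow(kept), 2)
  expect_setequal(kept$ic50_nM, c(250, 300))
  expect_warning(out <- filterByAffinity(data.frame(ic50_nM = c(NA, NA))),
                 "no records")
  expect_equal(nrow(out), 0)
  # max = Inf still drops only the missing record
  expect_equal(nrow(filterByAffinity(led, Inf)), 3)
  expect_identical(filterByAffinity(filterByAffinity(led)),
                   filterByAffinity(led))
})

test_that("inorganic filter keeps molecules with a carbon atom token", {
  mols <- data.frame(id = 1:6,
                     smiles = c("CCO", "[Na+].[Cl-]", "C(=O)=O", "ClCCl",
                                "[O-]S(=O)(=O)[O-]", "[13CH4]"))
  kept <- filterInorganic(mols)
  expect_setequal(kept$smiles, c("CCO", "C(=O)=O", "ClCCl", "[13CH4]"))
  expect_identical(filterInorganic(kept), kept)
})

test_that("sequence identity and greedy redundancy filtering behave", {
  expect_equal(sequenceIdentity("MKVLAG", "MKVLAG"), 1)
  expect_equal(sequenceIdentity("AAAA", "GGGG"), 0)
  seqs <- c(a = "MKVLAGWQERTYIPAS", b = "MKVLAGWQERTYIPAS")
  res <- filterRedundantTargets(seqs)
  expect_length(res$kept, 1)
  expect_equal(unname(res$clusters["b"]), names(res$kept))
  res2 <- filterRedundantTargets(c(x = "AAAAAAAA", y = "GGGGGGGG"))
  expect_length(res2$kept, 2)

  # 5-sequence toy set vs exhaustive pairwise identity + greedy sweep
  seqs5 <- c(s1 = "MKVLAGWQERTYIPASDFGH", s2 = "MKVLAGWQERTYIPASDFGA",
             s3 = "WWYYCCHHNNQQEEDDKKRR", s4 = "MKVLAGWQERTY",
             s5 = "PPPPGGGGSSSS")
  got <- filterRedundantTargets(seqs5, 0.75)
  idm <- outer(names(seqs5), names(seqs5),
               Vectorize(function(i, j) sequenceIdentity(seqs5[i], seqs5[j])))
  dimnames(idm) <- list(names(seqs5), names(seqs5))
  ord <- names(seqs5)[order(-nchar(seqs5), names(seqs5))]
  kept <- character()
  for (id in ord)
    if (!any(idm[id, kept] > 0.75)) kept <- c(kept, id)
  expect_setequal(names(got$kept), kept)
})

test_that("negative sampling avoids positives and exclusions, reproducibly", {
  pos <- data.frame(drug_id = c("d1", "d2"), target_id = c("t1", "t2"),
                    label = "positive")
  neg <- sampleNegatives(pos, c("d1", "d2", "d3"), c("t1", "t2"), 3, seed = 5)
  expect_equal(nrow(neg), 3)
  expect_false(any(paste(neg$drug_id, neg$target_id) %in%
                     paste(pos$drug_id, pos$target_id)))
  expect_false(any(duplicated(paste(neg$drug_id, neg$target_id))))
  neg2 <- sampleNegatives(pos, c("d1", "d2", "d3"), c("t1", "t2"), 3, seed = 5)
  expect_identical(neg, neg2)
  # an extra exclusion set shrinks the pool
  excl <- data.frame(drug_id = "d3", target_id = "t1")
  neg3 <- sampleNegatives(pos, c("d1", "d2", "d3"), c("t1", "t2"), 3,
                          seed = 5, exclusion = excl)
  expect_false("d3 t1" %in% paste(neg3$drug_id, neg3$target_id))
  # exhausted pool errors with its size
  posAll <- expand.grid(drug_id = c("a", "b"), target_id = c("u", "v"))
  posAll$label <- "positive"
  expect_error(sampleNegatives(posAll, c("a", "b"), c("u", "v"), 1),
               "pool too small")
})

test_that("temporal split matches rule-by-rule classification on a toy ledger", {
  cutoff <- as.Date("2016-04-20")
  set.seed(30)
  drugs <- data.frame(id = paste0("d", 1:6),
                      smiles = rep(c("CCO", "CCN", "c1ccccc1"), 2),
                      date_added = cutoff + c(-400, -30, 10, -100, 250, -5))
  tdates <- data.frame(id = paste0("t", 1:4),
                       date_added = cutoff + c(-300, -1, 60, -700))
  targets <- setNames(
    c("MKVLAGWQERTY", "AAAACCCCGGGG", "WWWWYYYYHHHH", "PPPPSSSSTTTT"),
    tdates$id)
  ints <- data.frame(
    drug_id = paste0("d", c(1, 1, 2, 3, 4, 5, 6, 2, 3, 5)),
    target_id = paste0("t", c(1, 3, 2, 1, 4, 2, 3, 4, 3, 3)),
    label = "positive",
    date_added = cutoff + c(-200, 40, -10, 15, 300, -2, 90, 33, 77, 400))
  # interactions cannot predate their endpoints in a real ledger; the split
  # must classify by entity age regardless, so leave dates as constructed
  split <- temporalSplit(drugs, targets, tdates, ints, cutoff)
  expect_named(split, paste0("dataset_", 1:5))

  dd <- setNames(drugs$date_added, drugs$id)
  td <- setNames(tdates$date_added, tdates$id)
  expectBucket <- vapply(seq_len(nrow(ints)), function(i)
    bruteTemporalBucket(dd[ints$drug_id[i]], td[ints$target_id[i]],
                        ints$date_added[i], cutoff), integer(1))
  for (b in 1:5) {
    got <- interactions(split[[b]])
    want <- ints[expectBucket == b, ]
    expect_equal(nrow(got), nrow(want))
    expect_setequal(paste(got$drug_id, got$target_id),
                    paste(want$drug_id, want$target_id))
  }
  # disjoint and exhaustive
  allPairs <- unname(unlist(lapply(split, function(s)
    paste(interactions(s)$drug_id, interactions(s)$target_id,
          interactions(s)$date_added))))
  expect_equal(sort(allPairs),
               sort(paste(ints$drug_id, ints$target_id, ints$date_added)))

  # all-old edge case: everything lands in dataset_1
  intsOld <- ints; intsOld$date_added <- cutoff - 500
  drugsOld <- drugs; drugsOld$date_added <- cutoff - 600
  tdOld <- tdates; tdOld$date_added <- cutoff - 600
  splitOld <- temporalSplit(drugsOld, targets, tdOld, intsOld, cutoff)
  expect_equal(nrow(interactions(splitOld$dataset_1)), nrow(ints))
  expect_true(all(vapply(splitOld[2:5],
                         function(s) nrow(interactions(s)) == 0, logical(1))))

  # old drug x new target goes to dataset_4 whatever the interaction date
  one <- data.frame(drug_id = "d1", target_id = "t3", label = "positive",
                    date_added = cutoff - 1000)
  s4 <- temporalSplit(drugs, targets, tdates, one, cutoff)
  expect_equal(nrow(interactions(s4$dataset_4)), 1)

  # missing dates are fatal and named
  badDrugs <- drugs; badDrugs$date_added[2] <- NA
  expect_error(temporalSplit(badDrugs, targets, tdates, ints, cutoff),
               "missing dates.*d2")
})

test_that("the synthetic generator plants class-matched positives", {
  cfgClean <- synthConfig(nClasses = 2, drugsPerClass = 6, targetsPerClass = 4,
                          labelNoise = 0, seed = 8)
  ds <- generateSynthetic(cfgClean)
  ints <- interactions(ds)
  dc <- attr(ds, "drugClasses"); tc <- attr(ds, "targetClasses")
  matched <- dc[ints$drug_id] == tc[ints$target_id]
  expect_true(all(ints$label[matched] == "positive"))
  expect_true(all(ints$label[!matched] == "negative"))
  # positives carry IC50 <= 300, generated SMILES round-trip tokenize
  expect_true(all(ints$ic50_nM[ints$label == "positive"] <= 300))
  for (s in drugs(ds)$smiles)
    expect_identical(paste(tokenizeSmiles(s), collapse = ""), s)

  # determinism
  expect_identical(interactions(generateSynthetic(cfgClean)), ints)

  # label-noise rate within 3 standard errors of epsilon
  cfgNoise <- synthConfig(nClasses = 2, drugsPerClass = 25,
                          targetsPerClass = 25, labelNoise = 0.05, seed = 9)
  dsn <- generateSynthetic(cfgNoise)
  intsn <- interactions(dsn)
  dcn <- attr(dsn, "drugClasses"); tcn <- attr(dsn, "targetClasses")
  truth <- dcn[intsn$drug_id] == tcn[intsn$target_id]
  flipped <- (intsn$label == "positive") != truth
  n <- length(flipped)
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(flipped) - 0.05), 3 * se)
})
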