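.popFromRecords <- function(df, nGenes = 50L)
  new("ModelPopulation", records = df, bestTrace = data.frame(),
      nGenes = nGenes)

test_that("gene frequencies equal direct counts", {
  # degenerate population of identical chromosomes
  rec <- data.frame(run = 1L, generation = 1L,
                    fitness = rep(0.9, 4), genes = rep("3,5,9", 4))
  fr <- geneFrequency(.popFromRecords(rec), topFraction = 1)
  expect_equal(fr$frequency, rep(1, 3))
  expect_setequal(fr$index, c(3L, 5L, 9L))

  # brute-force count at topFraction = 1
  set.seed(31)
  genes <- replicate(40, paste(sort(sample.int(20, 3)), collapse = ","))
  rec2 <- data.frame(run = 1L, generation = 1L,
                     fitness = runif(40), genes = genes)
  fr2 <- geneFrequency(.popFromRecords(rec2, 20L), 1)
  direct <- table(unlist(strsplit(genes, ",")))
  for (i in seq_len(nrow(fr2)))
    expect_equal(fr2$frequency[i],
                 unname(direct[as.character(fr2$index[i])]) / 40)

  # boundary ties are included in the top slice
  rec3 <- data.frame(run = 1L, generation = 1L,
                     fitness = c(1, 1, 1, 0.5),
                     genes = c("1,2", "1,3", "2,3", "4,5"))
  fr3 <- geneFrequency(.popFromRecords(rec3, 10L), topFraction = 0.25)
  expect_setequal(fr3$index, 1:3)  # all three tied models kept, not one
})

test_that("forward selection keeps only improving genes", {
  # a single perfectly predictive gene ranked first
  pair <- smallPair(nPatients = 30, nGenes = 20, nInformative = 1,
                    effectSize = 8, seed = 17)
  planted <- match(plantedGenes(pair$normal), geneIds(pair$normal))
  ranked <- c(planted, setdiff(seq_len(20), planted))
  rep1 <- forwardSelectRepresentative(ranked, pair$normal, "gleason",
                                      cvConfig(outerSplits = 10, seed = 2),
                                      maxSize = 5)
  expect_identical(modelGenes(rep1), geneIds(pair$normal)[planted])
  expect_gte(modelAccuracy(rep1, "inner"), 0.95)

  # an all-null ranked list stays far below maxSize, near chance accuracy
  sizes <- accs <- numeric(3)
  for (s in 1:3) {
    ds <- nullExprSet(n = 40, p = 20, seed = 50 + s)
    repN <- forwardSelectRepresentative(1:20, ds, "gleason",
                                        cvConfig(innerRepeats = 2,
                                                 outerSplits = 10,
                                                 seed = s),
                                        maxSize = 10)
    sizes[s] <- repN@size
    accs[s] <- modelAccuracy(repN, "outer")
  }
  expect_lte(mean(sizes), 5)
  expect_true(all(sizes <= 6))
  expect_lt(abs(mean(accs) - 0.5), 0.15)

  # duplicates in the ranked list are used at most once
  repD <- forwardSelectRepresentative(c(planted, planted, 2L, 2L),
                                      pair$normal, "gleason",
                                      cvConfig(outerSplits = 5, seed = 4),
                                      maxSize = 5)
  expect_false(anyDuplicated(modelGenes(repD)) > 0)

  # the representative is never worse than the top-ranked single gene
  accTop <- innerCVAccuracy(pair$normal, "gleason", ranked[1],
                            cvConfig(seed = 2))
  expect_gte(modelAccuracy(rep1, "inner") + 1e-9, accTop)
})

test_that("overlap significance follows the exact hypergeometric tail", {
  # zero overlap is never significant
  r0 <- overlapSignificance(paste0("a", 1:10), paste0("b", 1:10), 1000)
  expect_equal(r0$pValue, 1)

  # complete overlap of two top-50 lists from a universe of 1000
  ids <- paste0("g", 1:50)
  r1 <- overlapSignificance(ids, ids, 1000)
  expect_equal(log(r1$pValue), -lchoose(1000, 50), tolerance = 1e-12)
  expect_equal(r1$pValue, exactHyperTail(50, 1000, 50, 50),
               tolerance = 1e-9)

  # monotone decreasing in the overlap
  ps <- vapply(0:20, function(ov) {
    a <- c(paste0("s", seq_len(ov)), paste0("a", seq_len(50 - ov)))
    b <- c(paste0("s", seq_len(ov)), paste0("b", seq_len(50 - ov)))
    overlapSignificance(a, b, 1000)$pValue
  }, numeric(1))
  expect_true(all(diff(ps) < 0))

  # expected overlap under independence matches simulation
  set.seed(60)
  sim <- vapply(1:10000, function(i)
    length(intersect(sample.int(1000, 50), sample.int(1000, 50))),
    numeric(1))
  expect_lt(abs(mean(sim) - r1$expected), 0.1)
  expect_equal(r1$expected, 2.5)

  expect_error(overlapSignificance(paste0("a", 1:10), "a1", 5), "universe")
})

test_that("GA and BVS representatives largely agree on a strong signal", {
  pair <- smallPair(nPatients = 60, nGenes = 100, nInformative = 5,
                    effectSize = 3, seed = 37)
  ds <- pair$normal
  pop <- gaEvolve(ds, "gleason",
                  gaConfig(populationSize = 20, generations = 8,
                           nRuns = 20, goalAccuracy = 0.99, seed = 11),
                  cvConfig(innerRepeats = 2, seed = 11))
  fr <- geneFrequency(pop, 0.05, geneIds(ds))
  gaRep <- forwardSelectRepresentative(
    fr$index, ds, "gleason",
    cvConfig(innerRepeats = 8, outerSplits = 10, seed = 12),
    maxSize = 5, tolerance = 0.02)
  cfg <- bvsConfig(nIterations = 6000, burnIn = 1000,
                   expectedModelSize = 5, seed = 13)
  chains <- lapply(13:14, function(s) bvsChain(ds, "gleason", cfg, s))
  bvsRep <- poolChains(chains, ds, "gleason", seed = 15)
  shared <- length(intersect(modelGenes(gaRep), modelGenes(bvsRep)))
  expect_gte(shared / min(gaRep@size, bvsRep@size), 0.5)
})
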