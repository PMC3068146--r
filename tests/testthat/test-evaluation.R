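# A fast deterministic selector for specificity tests: top-k by F ratio.
fastSelector <- univariateSelector(5)

test_that("identical compartments give matching same/cross accuracies", {
  pair <- smallPair(nPatients = 40, nGenes = 60, nInformative = 5,
                    effectSize = 2, seed = 3)
  # tumour replaced by a literal copy of the normal data
  copy <- pair$normal
  SummarizedExperiment::colData(copy)$tissue <- "tumour"
  res <- specificityTest(pair$normal, copy, "gleason",
                         selector = fastSelector, nRepeats = 8, seed = 5)
  expect_lt(abs(mean(sameTissueAccuracy(res)) -
                  mean(crossTissueAccuracy(res))), 0.1)
})

test_that("shared signal in both tissues transfers across compartments", {
  pair <- smallPair(nPatients = 60, nGenes = 100, nInformative = 5,
                    effectSize = 2, signalTissue = "both", seed = 8)
  res <- specificityTest(pair$normal, pair$tumour, "gleason",
                         selector = fastSelector, nRepeats = 6, seed = 2)
  expect_gte(mean(crossTissueAccuracy(res)), 0.85)
})

test_that("tissue-specific signal does not transfer", {
  pair <- smallPair(nPatients = 60, nGenes = 100, nInformative = 5,
                    effectSize = 2, signalTissue = "normal", seed = 12)
  res <- specificityTest(pair$normal, pair$tumour, "gleason",
                         selector = fastSelector, nRepeats = 10, seed = 4)
  expect_gte(mean(sameTissueAccuracy(res)), 0.85)
  cross <- mean(crossTissueAccuracy(res))
  # chance level within 3 binomial standard errors
  se <- 0.5 / sqrt(10 * 20)
  expect_lt(abs(cross - 0.5), max(3 * se, 0.11))
})

test_that("the swap protocol is symmetric on symmetric data", {
  sameMeans <- matrix(0, 2, 20)
  for (s in 1:20) {
    pair <- smallPair(nPatients = 30, nGenes = 40, nInformative = 4,
                      effectSize = 1.5, signalTissue = "both",
                      seed = 500 + s)
    rN <- specificityTest(pair$normal, pair$tumour, "gleason",
                          selector = fastSelector, nRepeats = 2,
                          seed = s)
    rT <- specificityTest(pair$normal, pair$tumour, "gleason",
                          signatureTissue = "tumour",
                          selector = fastSelector, nRepeats = 2,
                          seed = s)
    sameMeans[, s] <- c(mean(sameTissueAccuracy(rN)),
                        mean(sameTissueAccuracy(rT)))
  }
  expect_gt(t.test(sameMeans[1, ], sameMeans[2, ], paired = TRUE)$p.value,
            0.01)
})

test_that("unpaired datasets are rejected", {
  pair <- smallPair(nPatients = 10, seed = 2)
  other <- generatePaired(syntheticConfig(nPatients = 12, nGenes = 60,
                                          nInformative = 5, seed = 3))
  expect_error(specificityTest(pair$normal, other$tumour, "gleason",
                               selector = fastSelector),
               "not paired")
})

test_that("rank-one data has the closed-form loading profile", {
  base <- rnorm(30)
  ds <- toyExprSet(cbind(base, -base), labels = rep_len(c(0, 1), 30))
  pc <- pcaContributions(ds, 1:2, nComponents = 2)
  p1 <- pc$profiles[[1]]
  expect_equal(abs(unname(p1@loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-12)
  expect_equal(p1@explainedVariance, 1, tolerance = 1e-12)
})

test_that("loadings match a direct eigendecomposition", {
  pair <- smallPair(nPatients = 25, nGenes = 30, seed = 14)
  genes <- 1:8
  pc <- pcaContributions(pair$normal, genes, nComponents = 4)
  X <- t(exprMatrix(pair$normal))[, genes]
  ev <- eigenLoadings(X)
  tot <- sum(ev$values)
  for (j in 1:4) {
    got <- unname(pc$profiles[[j]]@loadings)
    want <- ev$vectors[, j]
    if (sign(want[which.max(abs(want))]) < 0) want <- -want
    expect_equal(got, want, tolerance = 1e-8)
    expect_equal(pc$profiles[[j]]@explainedVariance, ev$values[j] / tot,
                 tolerance = 1e-8)
  }
})

test_that("scores and loadings are stable under gene reordering", {
  pair <- smallPair(nPatients = 20, nGenes = 25, seed = 16)
  g <- c(3L, 7L, 11L, 15L)
  a <- pcaContributions(pair$normal, g, 2)
  b <- pcaContributions(pair$normal, rev(g), 2)
  for (j in 1:2) {
    la <- a$profiles[[j]]@loadings
    lb <- b$profiles[[j]]@loadings[names(la)]
    expect_equal(abs(unname(la)), abs(unname(lb)), tolerance = 1e-9)
    expect_equal(abs(a$scores[, j]), abs(b$scores[, j]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("planted genes dominate the class-separating component", {
  pair <- smallPair(nPatients = 60, nGenes = 100, nInformative = 5,
                    effectSize = 2, seed = 18)
  planted <- plantedGenes(pair$normal)
  pc <- pcaContributions(pair$normal, planted, nComponents = 1)
  expect_true(all(abs(pc$profiles[[1]]@loadings) > 0.3))
  expect_setequal(pc$profiles[[1]]@highlighted, planted)
})

test_that("constant genes are dropped with a warning", {
  vals <- cbind(rnorm(12), rep(1, 12), rnorm(12))
  ds <- toyExprSet(vals, labels = rep_len(c(0, 1), 12))
  expect_warning(pc <- pcaContributions(ds, 1:3, 2), "constant")
  expect_length(pc$profiles[[1]]@loadings, 2)
  ds2 <- toyExprSet(cbind(rep(1, 12), rep(2, 12)),
                    labels = rep_len(c(0, 1), 12))
  expect_error(suppressWarnings(pcaContributions(ds2, 1:2, 1)),
               "non-constant")
})
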