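test_that("analytic marginal likelihood matches numeric integration", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    nGenes <- 5
    k <- sample(0:2, 1)  # plus the always-included intercept: dim <= 3
    X <- matrix(rnorm(n * nGenes), n, nGenes)
    z <- rnorm(n)
    gamma <- if (k > 0) sample(nGenes, k) else integer()
    c0 <- sample(c(1, 5, 10), 1)
    got <- bvsLogMarginal(X, z, gamma, priorScale = c0)
    want <- numericLogMarginal(cbind(1, X[, gamma, drop = FALSE]), z, c0)
    expect_lt(abs(got - want), 1e-6)
  }
})

test_that("a no-move proposal has likelihood ratio one", {
  set.seed(3)
  X <- matrix(rnorm(40), 10, 4)
  z <- rnorm(10)
  g <- c(1L, 3L)
  expect_identical(bvsLogMarginal(X, z, g, 10) -
                     bvsLogMarginal(X, z, g, 10), 0)
})

test_that("chains are deterministic and respect the latent sign constraint", {
  pair <- smallPair(nPatients = 16, nGenes = 20, seed = 5)
  cfg <- bvsConfig(nIterations = 400, burnIn = 100,
                   expectedModelSize = 3, seed = 9)
  a <- bvsChain(pair$normal, "gleason", cfg, chainSeed = 9)
  b <- bvsChain(pair$normal, "gleason", cfg, chainSeed = 9)
  expect_identical(visitedSubsets(a), visitedSubsets(b))
  expect_identical(marginalInclusion(a), marginalInclusion(b))
  expect_identical(sum(visitedSubsets(a)$visits), 300L)
  expect_true(all(marginalInclusion(a) >= 0 & marginalInclusion(a) <= 1))
})

test_that("the inclusion prior is calibrated to the expected model size", {
  # prior simulation: gamma_j ~ Bernoulli(expectedModelSize / nGenes)
  set.seed(40)
  sizes <- vapply(1:4000, function(i) sum(runif(200) < 5 / 200),
                  numeric(1))
  expect_lt(abs(mean(sizes) - 5), 0.15)

  # on null data with an informative coefficient prior the posterior
  # shrinks below the prior mean (Occam) without freezing entirely
  ds <- nullExprSet(n = 30, p = 50, seed = 41)
  cfg <- bvsConfig(nIterations = 4000, burnIn = 1000,
                   expectedModelSize = 5, seed = 2)
  ch <- bvsChain(ds, "gleason", cfg, chainSeed = 2)
  expect_lt(mean(ch@trace$size), 5)
  expect_gt(mean(ch@trace$size), 0.05)

  # in the no-evidence limit (coefficient prior scale -> 0) the sampler
  # must reproduce its Bernoulli(expectedModelSize / nGenes) prior exactly:
  # this checks both proposal symmetry and the prior-size calibration
  chP <- bvsChain(ds, "gleason",
                  bvsConfig(nIterations = 4000, burnIn = 1000,
                            expectedModelSize = 5, priorScale = 1e-8,
                            seed = 3), chainSeed = 3)
  expect_lt(abs(mean(chP@trace$size) - 5), 1.5)
  miP <- marginalInclusion(chP)
  expect_lt(max(miP) / min(miP), 3)
})

test_that("planted genes dominate the marginal inclusion ranking", {
  pair <- smallPair(nPatients = 40, nGenes = 100, nInformative = 5,
                    effectSize = 2, seed = 19)
  planted <- plantedGenes(pair$normal)
  cfg <- bvsConfig(nIterations = 6000, burnIn = 1000,
                   expectedModelSize = 5, seed = 7)
  ch <- bvsChain(pair$normal, "gleason", cfg, chainSeed = 7)
  mi <- marginalInclusion(ch)
  others <- mi[setdiff(names(mi), planted)]
  expect_gt(mean(mi[planted]), quantile(others, 0.99))
})

test_that("non-binary endpoints are rejected", {
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  ds <- ExprSet(m, tissue = "normal", patientId = paste0("P", 1:10),
                labels = list(gleason = rep(0L, 10)))
  expect_error(bvsChain(ds, "gleason"), "binary endpoint")
})

test_that("chain pooling is order-invariant with sensible tie-breaks", {
  pair <- smallPair(nPatients = 30, nGenes = 40, nInformative = 3,
                    effectSize = 3, seed = 23)
  cfg <- bvsConfig(nIterations = 2000, burnIn = 500,
                   expectedModelSize = 3, seed = 5)
  c1 <- bvsChain(pair$normal, "gleason", cfg, chainSeed = 5)
  c2 <- bvsChain(pair$normal, "gleason", cfg, chainSeed = 6)

  # singleton pool returns the only (non-null) candidate
  one <- new("ChainSummary",
             visitedSubsets = data.frame(subset = "2,7", visits = 10L),
             marginalInclusion = setNames(numeric(40),
                                          geneIds(pair$normal)),
             trace = data.frame(), nIterations = 11L, burnIn = 1L)
  rep1 <- poolChains(list(one), pair$normal, "gleason", seed = 4)
  expect_identical(modelGenes(rep1), geneIds(pair$normal)[c(2, 7)])

  # identical chains pool to the single-chain result
  expect_identical(modelGenes(poolChains(list(c1), pair$normal, "gleason",
                                         seed = 4)),
                   modelGenes(poolChains(list(c1, c1), pair$normal,
                                         "gleason", seed = 4)))

  # chain order does not matter
  expect_identical(modelGenes(poolChains(list(c1, c2), pair$normal,
                                         "gleason", seed = 4)),
                   modelGenes(poolChains(list(c2, c1), pair$normal,
                                         "gleason", seed = 4)))
})

test_that("pooling prefers the subset carrying the complete planted signal", {
  pair <- smallPair(nPatients = 40, nGenes = 30, nInformative = 3,
                    effectSize = 3, seed = 29)
  planted <- match(plantedGenes(pair$normal), geneIds(pair$normal))
  noise <- setdiff(seq_len(30), planted)[1:3]
  mk <- function(genes, visits) new("ChainSummary",
    visitedSubsets = data.frame(
      subset = paste(sort(genes), collapse = ","), visits = visits),
    marginalInclusion = setNames(numeric(30), geneIds(pair$normal)),
    trace = data.frame(), nIterations = visits + 1L, burnIn = 1L)
  win <- poolChains(list(mk(planted, 50L), mk(noise, 80L)),
                    pair$normal, "gleason", seed = 8)
  expect_setequal(modelGenes(win), geneIds(pair$normal)[planted])
})
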