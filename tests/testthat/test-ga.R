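test_that("initial populations sample chromosomes uniformly", {
  cfg <- gaConfig(populationSize = 10000L, chromosomeSize = 5L, seed = 3)
  pop <- initPopulation(cfg, 500L)
  expect_true(all(vapply(pop, function(g)
    length(unique(g)) == 5L && all(g >= 1 & g <= 500), logical(1))))
  freq <- tabulate(unlist(pop), 500) / 10000
  expect_equal(mean(freq), 0.01, tolerance = 1e-12)  # 5/500 exactly
  expect_true(all(abs(freq - 0.01) < 0.005))
  expect_gt(mean(abs(freq - 0.01) < 0.003), 0.99)

  # forced full set and determinism
  tiny <- gaConfig(populationSize = 3L, chromosomeSize = 4L, seed = 1)
  expect_true(all(vapply(initPopulation(tiny, 4L), identical, logical(1),
                         1:4)))
  expect_identical(initPopulation(cfg, 500L), initPopulation(cfg, 500L))
  expect_error(initPopulation(tiny, 3L), "chromosomeSize")
})

test_that("duplicate repair keeps chromosomes valid sets", {
  set.seed(4)
  for (i in 1:200) {
    raw <- sample.int(20, 6, replace = TRUE)
    rep <- TissueSig:::.repairChromosome(raw, 20)
    expect_length(rep, 6)
    expect_false(anyDuplicated(rep) > 0)
    expect_true(all(rep %in% 1:20))
    # loci that were not duplicated are untouched
    expect_true(all(raw[!duplicated(raw)] %in% rep))
  }
})

test_that("evolved populations never contain duplicate genes", {
  pair <- smallPair(nPatients = 20, nGenes = 30, seed = 6)
  pop <- gaEvolve(pair$normal, "gleason",
                  gaConfig(populationSize = 12, generations = 6,
                           nRuns = 2, mutationRate = 0.2, seed = 8),
                  cvConfig(seed = 8))
  for (g in strsplit(modelRecords(pop)$genes, ","))
    expect_false(anyDuplicated(as.integer(g)) > 0)
})

test_that("elitism makes the best fitness non-decreasing", {
  pair <- smallPair(nPatients = 24, nGenes = 40, seed = 10)
  # the pure-elitist limit: no variation operators at all
  cfg <- gaConfig(populationSize = 10, generations = 8, mutationRate = 0,
                  crossoverRate = 0, elitism = 9L, nRuns = 1, seed = 2)
  pop <- gaEvolve(pair$normal, "gleason", cfg, cvConfig(seed = 2))
  tr <- pop@bestTrace
  expect_true(all(diff(tr$best_fitness) >= 0))

  # general elitism >= 1 with active operators, several seeds
  for (s in 1:3) {
    cfg2 <- gaConfig(populationSize = 12, generations = 6, nRuns = 2,
                     mutationRate = 0.05, elitism = 2L, seed = s)
    tr2 <- gaEvolve(pair$normal, "gleason", cfg2, cvConfig(seed = s))@bestTrace
    for (r in unique(tr2$run))
      expect_true(all(diff(tr2$best_fitness[tr2$run == r]) >= 0))
  }
})

test_that("an unreachable goal exhausts generations and returns the population", {
  ds <- nullExprSet(n = 20, p = 25, seed = 15)
  cfg <- gaConfig(populationSize = 10, generations = 5, goalAccuracy = 1.0,
                  nRuns = 1, seed = 5)
  pop <- gaEvolve(ds, "gleason", cfg, cvConfig(seed = 5))
  expect_identical(nrow(modelRecords(pop)), 10L)
  expect_identical(max(pop@bestTrace$generation), 5L)
  expect_lt(max(modelRecords(pop)$fitness), 1.0)
})

test_that("the GA is deterministic and recovers planted genes", {
  pair <- smallPair(nPatients = 40, nGenes = 100, nInformative = 5,
                    effectSize = 2, seed = 20)
  cfg <- gaConfig(populationSize = 20, generations = 8, nRuns = 10,
                  goalAccuracy = 0.99, seed = 44)
  cv <- cvConfig(innerRepeats = 2, seed = 44)
  pop <- gaEvolve(pair$normal, "gleason", cfg, cv)
  pop2 <- gaEvolve(pair$normal, "gleason", cfg, cv)
  expect_identical(modelRecords(pop), modelRecords(pop2))

  planted <- plantedGenes(pair$normal)
  bestPerRun <- vapply(split(modelRecords(pop), modelRecords(pop)$run),
                       function(d) d$genes[which.max(d$fitness)],
                       character(1))
  union <- unique(unlist(strsplit(bestPerRun, ",")))
  hits <- sum(planted %in% geneIds(pair$normal)[as.integer(union)])
  expect_gte(hits, 4)
})

test_that("outer annotation matches outerAccuracy and shows selection bias", {
  pair <- smallPair(nPatients = 30, nGenes = 40, seed = 3)
  # singleton population: annotation equals a direct outer estimate
  rec <- data.frame(run = 1L, generation = 1L, fitness = 0.8,
                    genes = "1,2,3")
  pop <- new("ModelPopulation", records = rec,
             bestTrace = data.frame(), nGenes = 40L)
  cv <- cvConfig(outerSplits = 10, seed = 6)
  ann <- finalPopulationAccuracy(pop, pair$normal, "gleason", cv)
  direct <- outerAccuracy(pair$normal, "gleason", 1:3,
                          cvConfig(outerSplits = 10,
                                   seed = TissueSig:::deriveSeed(6, 1)))
  expect_equal(ann@records$outer_mean, direct$mean)

  # after selection the outer estimate is on average below the inner one
  diffs <- vapply(1:6, function(s) {
    ds <- nullExprSet(n = 30, p = 40, seed = 300 + s)
    pop <- gaEvolve(ds, "gleason",
                    gaConfig(populationSize = 10, generations = 5,
                             nRuns = 1, seed = s), cvConfig(seed = s))
    rec <- modelRecords(pop)
    best <- rec[which.max(rec$fitness), ]
    genes <- as.integer(strsplit(best$genes, ",")[[1]])
    outer <- outerAccuracy(ds, "gleason", genes,
                           cvConfig(outerSplits = 15, seed = s))$mean
    best$fitness - outer
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
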