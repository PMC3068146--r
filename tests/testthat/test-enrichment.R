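test_that("network score equals the exact hypergeometric right tail", {
  # whole-tail edge
  s0 <- networkScore(100, 10, 5, 0)
  expect_equal(s0@pRight, 1)
  expect_equal(pathwayScore(s0), 0)

  # exact rational enumeration for assorted (N, G, s, f) with N <= 60
  cases <- list(c(20, 5, 5, 3), c(60, 20, 15, 9), c(45, 12, 8, 2),
                c(60, 30, 30, 20), c(33, 11, 7, 7))
  for (cs in cases) {
    got <- networkScore(cs[1], cs[2], cs[3], cs[4])@pRight
    want <- exactHyperTail(cs[4], cs[1], cs[2], cs[3])
    expect_equal(got, want, tolerance = 1e-12)
  }

  # monotone: more focus genes in the pathway never lowers the score
  scores <- vapply(0:10, function(f)
    pathwayScore(networkScore(1000, 40, 10, f)), numeric(1))
  expect_true(all(diff(scores) >= 0))

  expect_error(networkScore(100, 10, 5, 6), "f must not exceed")
  expect_error(networkScore(100, 150, 5, 2), "must not exceed N")
})

test_that("score greater than 5 is exactly the p < 1e-5 filter", {
  set.seed(2)
  for (i in 1:200) {
    N <- sample(50:2000, 1)
    G <- sample(5:min(100, N - 1), 1)
    s <- sample(5:min(50, N - 1), 1)
    f <- sample(0:min(G, s), 1)
    sp <- networkScore(N, G, s, f)
    expect_identical(pathwayScore(sp) > 5, sp@pRight < 1e-5)
  }
})

test_that("the score agrees with the right-tailed Fisher test", {
  # the 2x2 table [f, G-f; s-f, N-G-s+f] encodes the same tail
  cases <- list(c(200, 30, 20, 8), c(500, 50, 35, 3), c(80, 10, 12, 5))
  for (cs in cases) {
    N <- cs[1]; G <- cs[2]; s <- cs[3]; f <- cs[4]
    tab <- matrix(c(f, G - f, s - f, N - G - s + f), 2, 2)
    pFisher <- fisherPathwayTest(tab)$pValue
    expect_equal(networkScore(N, G, s, f)@pRight, pFisher,
                 tolerance = 1e-9)
  }

  # degenerate margins and exact extreme table
  expect_equal(fisherPathwayTest(matrix(c(0, 5, 7, 3), 2))$pValue, 1)
  expect_equal(fisherPathwayTest(matrix(c(0, 0, 4, 9), 2))$pValue, 1)
  p <- fisherPathwayTest(matrix(c(10, 0, 0, 10), 2))$pValue
  expect_equal(p, 1 / choose(20, 10), tolerance = 1e-12)
  expect_error(fisherPathwayTest(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("gene-set scoring handles GMT input end to end", {
  pair <- smallPair(nPatients = 20, nGenes = 50, nInformative = 5, seed = 6)
  ds <- pair$normal
  planted <- plantedGenes(ds)
  gmt <- file.path(tempdir(), "score.gmt")
  writeLines(c(
    paste(c("hit_set", "na", planted, geneIds(ds)[1:2]), collapse = "\t"),
    paste(c("null_set", "na", setdiff(geneIds(ds), planted)[1:7]),
          collapse = "\t")), gmt)
  tab <- scoreGeneSets(planted, readGMT(gmt), geneIds(ds))
  expect_identical(tab$set[1], "hit_set")
  expect_gt(tab$score[1], tab$score[2])
  expect_identical(tab$pass_score_gt_5, tab$p < 1e-5)
})

test_that("one-way ANOVA matches its two-group identity and detects shifts", {
  set.seed(9)
  vals <- matrix(rnorm(30 * 3), 30, 3)
  ds <- toyExprSet(vals, labels = rep_len(c(0, 1), 30))
  groups <- rep(c("A", "B"), each = 15)

  a <- anovaByGroup(ds, 1L, groups)
  tt <- t.test(vals[groups == "A", 1], vals[groups == "B", 1],
               var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$pValue, tt$p.value, tolerance = 1e-9)
  expect_named(a$groupMeans, c("A", "B"))

  # a strongly shifted group is detected
  shifted <- vals
  shifted[groups == "B", 2] <- shifted[groups == "B", 2] + 5
  dsS <- toyExprSet(shifted, labels = rep_len(c(0, 1), 30))
  expect_lt(anovaByGroup(dsS, 2L, groups)$pValue, 1e-6)

  expect_error(anovaByGroup(ds, 1L, c(rep("A", 29), "B")),
               "fewer than 2")
  expect_error(anovaByGroup(ds, 1L, rep("A", 30)), "two groups")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(77)
  groups <- rep(c("N", "adj", "PIN", "PCA"), each = 6)
  ps <- vapply(1:2000, function(i) {
    ds <- toyExprSet(matrix(rnorm(24), 24, 1),
                     labels = rep_len(c(0, 1), 24))
    anovaByGroup(ds, 1L, groups)$pValue
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("univariate ranking recovers planted genes and handles nulls", {
  pair <- smallPair(nPatients = 40, nGenes = 80, nInformative = 5,
                    effectSize = 3, seed = 11)
  planted <- plantedGenes(pair$normal)
  rk <- univariateRank(pair$normal, "gleason")
  expect_setequal(head(rk$gene, 5), planted)
  expect_true(all(diff(rk$F) <= 0))
  # F equals the squared t statistic
  expect_equal(rk$F, rk$t^2, tolerance = 1e-12)

  # permuting the labels destroys the enrichment
  ds <- pair$normal
  perm <- withr::with_seed(5, sample(unname(endpointLabels(ds, "gleason"))))
  SummarizedExperiment::colData(ds)$gleason <- perm
  rkP <- univariateRank(ds, "gleason")
  expect_gt(mean(match(planted, rkP$gene)), 80 / 4)

  # constant genes rank last with F = 0
  m <- exprMatrix(pair$normal)
  m[3, ] <- 1
  dsC <- ExprSet(m, tissue = "normal",
                 patientId = patientIds(pair$normal),
                 labels = list(gleason =
                   unname(endpointLabels(pair$normal, "gleason"))))
  rkC <- univariateRank(dsC, "gleason")
  expect_identical(rkC$gene[80], geneIds(dsC)[3])
  expect_identical(rkC$F[80], 0)
})
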