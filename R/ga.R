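#' Random initial chromosome population
#'
#' Each chromosome is a fixed-size set of distinct gene indices sampled
#' uniformly without replacement from the gene universe.
#'
#' @param cfg a [GAConfig-class].
#' @param nGenes size of the gene universe.
#' @param seed RNG seed (default the config's).
#' @return List of integer vectors of length `cfg@chromosomeSize`.
#' @export
initPopulation <- function(cfg, nGenes, seed = cfg@seed) {
  if (cfg@chromosomeSize > nGenes)
    stop("invalid config: chromosomeSize exceeds the number of genes")
  withSeed(seed, replicate(cfg@populationSize,
                           sort(sample.int(nGenes, cfg@chromosomeSize)),
                           simplify = FALSE))
}

# Replace duplicate loci with uniform random unused genes; keeps length.
.repairChromosome <- function(genes, nGenes) {
  dup <- duplicated(genes)
  if (any(dup)) {
    free <- setdiff(seq_len(nGenes), genes)
    genes[dup] <- free[sample.int(length(free), sum(dup))]
  }
  genes
}

# Single GA run on precomputed matrices; uses the current RNG stream.
# Fitness = inner-CV accuracy on folds fixed for the run, cached per subset.
.gaRun <- function(X, y, cfg, cv, runId) {
  nGenes <- ncol(X)
  # fold partitions are fixed for the whole run so fitness is a
  # deterministic function of the subset (elitism then guarantees a
  # non-decreasing best fitness); innerRepeats > 1 averages several
  # partitions, damping fold-assignment noise in the fitness signal
  foldsList <- lapply(seq_len(cv@innerRepeats), function(r)
    .foldsWithAllClasses(y, cv@innerK, cv@stratified))
  foldsMat <- do.call(cbind, foldsList)
  y01 <- match(y, sort(unique(y))) - 1L
  cache <- new.env(parent = emptyenv())
  fitnessAll <- function(pop) {
    keys <- vapply(pop, function(g) paste(g, collapse = ","), character(1))
    newIdx <- which(!vapply(keys, function(k)
      !is.null(cache[[k]]), logical(1)))
    if (length(newIdx)) {
      vals <- .cppBatchCV(X, y01, foldsMat, pop[newIdx])
      for (j in seq_along(newIdx)) cache[[keys[newIdx[j]]]] <- vals[j]
    }
    vapply(keys, function(k) cache[[k]], numeric(1), USE.NAMES = FALSE)
  }

  pop <- replicate(cfg@populationSize,
                   sort(sample.int(nGenes, cfg@chromosomeSize)),
                   simplify = FALSE)
  fitness <- fitnessAll(pop)
  bestTrace <- data.frame(run = integer(), generation = integer(),
                          best_fitness = numeric())
  lastGen <- 0L
  for (gen in seq_len(cfg@generations)) {
    lastGen <- gen
    ord <- order(fitness, decreasing = TRUE)
    bestTrace <- rbind(bestTrace, data.frame(
      run = runId, generation = gen, best_fitness = fitness[ord[1L]]))
    if (fitness[ord[1L]] >= cfg@goalAccuracy) break
    if (gen == cfg@generations) break

    # linear-rank parent selection: best gets the highest weight
    ranks <- integer(cfg@populationSize)
    ranks[ord] <- cfg@populationSize:1L
    selProb <- ranks / sum(ranks)

    elite <- pop[ord][seq_len(cfg@elitism)]
    nChildren <- cfg@populationSize - cfg@elitism
    children <- vector("list", nChildren)
    i <- 1L
    while (i <= nChildren) {
      parents <- sample.int(cfg@populationSize, 2L, replace = TRUE,
                            prob = selProb)
      p1 <- pop[[parents[1L]]]
      p2 <- pop[[parents[2L]]]
      if (runif(1) < cfg@crossoverRate && cfg@chromosomeSize > 1L) {
        cut <- sample.int(cfg@chromosomeSize - 1L, 1L)
        c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):cfg@chromosomeSize])
        c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):cfg@chromosomeSize])
      } else {
        c1 <- p1
        c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > nChildren) break
        child <- .repairChromosome(child, nGenes)
        mut <- runif(cfg@chromosomeSize) < cfg@mutationRate
        if (any(mut)) {
          free <- setdiff(seq_len(nGenes), child)
          child[mut] <- free[sample.int(length(free), sum(mut))]
        }
        children[[i]] <- sort(child)
        i <- i + 1L
      }
    }
    pop <- c(elite, children)
    fitness <- fitnessAll(pop)
  }
  list(pop = pop, fitness = fitness, bestTrace = bestTrace,
       generation = lastGen)
}

#' Evolve gene-subset classifiers by genetic algorithm
#'
#' Runs `cfg@nRuns` independent GA searches over fixed-size gene subsets,
#' each maximising the inner-CV discriminant accuracy (the first
#' cross-validation level), and pools every final-population chromosome into
#' one [ModelPopulation-class]. A run stops early once its best fitness
#' reaches `cfg@goalAccuracy`. The whole search is deterministic given
#' `cfg@seed`: per-run seeds are derived from the master seed.
#'
#' @param ds an [ExprSet-class].
#' @param endpoint endpoint name.
#' @param cfg a [GAConfig-class].
#' @param cv a [CVConfig-class] for the inner (fitness) level.
#' @return A [ModelPopulation-class]; `records` holds one row per
#'   final-population chromosome across runs.
#' @seealso [finalPopulationAccuracy()] to attach the second-level outer
#'   estimates, [geneFrequency()] / [forwardSelectRepresentative()] to
#'   distil a representative model.
#' @export
gaEvolve <- function(ds, endpoint, cfg = gaConfig(), cv = cvConfig()) {
  validObject(cfg)
  if (cfg@chromosomeSize > nrow(ds))
    stop("invalid config: chromosomeSize exceeds the number of genes")
  X <- designMatrix(ds, seq_len(nrow(ds)))
  y <- unname(endpointLabels(ds, endpoint))
  records <- vector("list", cfg@nRuns)
  traces <- vector("list", cfg@nRuns)
  for (r in seq_len(cfg@nRuns)) {
    res <- withSeed(deriveSeed(cfg@seed, r),
                    .gaRun(X, y, cfg, cv, runId = r))
    records[[r]] <- data.frame(
      run = r, generation = res$generation, fitness = res$fitness,
      genes = vapply(res$pop, paste, character(1), collapse = ","))
    traces[[r]] <- res$bestTrace
  }
  new("ModelPopulation", records = do.call(rbind, records),
      bestTrace = do.call(rbind, traces), nGenes = nrow(ds))
}

#' Attach outer-split accuracies to a model population
#'
#' The second cross-validation level: every distinct chromosome in the
#' population is re-scored on the entire dataset by repeated stratified
#' random splits (default 40 splits, 2/3 train / 1/3 test) and annotated
#' with the mean and standard deviation of its per-split accuracies.
#'
#' @param pop a [ModelPopulation-class].
#' @inheritParams gaEvolve
#' @param cv a [CVConfig-class] for the outer level.
#' @return The population with `outer_mean` and `outer_sd` columns added.
#' @export
finalPopulationAccuracy <- function(pop, ds, endpoint, cv = cvConfig()) {
  if (nrow(pop@records) == 0L) stop("empty model population")
  keys <- unique(pop@records$genes)
  outm <- numeric(length(keys))
  outs <- numeric(length(keys))
  for (i in seq_along(keys)) {
    genes <- as.integer(strsplit(keys[i], ",")[[1L]])
    oc <- outerAccuracy(ds, endpoint, genes,
                        cvConfig(innerK = cv@innerK,
                                 outerSplits = cv@outerSplits,
                                 trainFraction = cv@trainFraction,
                                 stratified = cv@stratified,
                                 seed = deriveSeed(cv@seed, i)))
    outm[i] <- oc$mean
    outs[i] <- stats::sd(oc$perSplit)
  }
  idx <- match(pop@records$genes, keys)
  pop@records$outer_mean <- outm[idx]
  pop@records$outer_sd <- outs[idx]
  pop
}

#' Write a model population to a TSV dump
#'
#' @param pop a [ModelPopulation-class].
#' @param ds the dataset the population was evolved on (for gene ids).
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeModelPopulation <- function(pop, ds, path) {
  rec <- pop@records
  ids <- geneIds(ds)
  rec$gene_ids <- vapply(strsplit(rec$genes, ","), function(g)
    paste(ids[as.integer(g)], collapse = ","), character(1))
  write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
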