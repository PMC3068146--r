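# Small dataset builders shared across tests.

# ExprSet from an explicit samples x genes value matrix.
toyExprSet <- function(values, labels, tissue = "normal",
                       endpoint = "gleason") {
  values <- as.matrix(values)
  n <- nrow(values)
  m <- t(values)
  rownames(m) <- sprintf("g%04d", seq_len(nrow(m)))
  colnames(m) <- sprintf("S%03d", seq_len(n))
  lab <- list()
  lab[[endpoint]] <- as.integer(labels)
  ExprSet(m, tissue = tissue, patientId = sprintf("P%03d", seq_len(n)),
          labels = lab)
}

# Random Gaussian dataset with labels independent of the data.
nullExprSet <- function(n = 30, p = 20, seed = 1, tissue = "normal") {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n * p), n, p)
    labs <- rep_len(c(0L, 1L), n)
    toyExprSet(vals, labs, tissue = tissue)
  })
}

# Paired datasets at the package's default study conditions, scaled down.
smallPair <- function(nPatients = 30, nGenes = 60, nInformative = 5,
                      effectSize = 2, signalTissue = "normal", seed = 1,
                      ...) {
  generatePaired(syntheticConfig(
    nPatients = nPatients, nGenes = nGenes, nInformative = nInformative,
    effectSize = effectSize, signalTissue = signalTissue, seed = seed,
    blockSize = min(10L, nGenes), ...))
}

plantedGenes <- function(ds, endpoint = "gleason") {
  S4Vectors::metadata(ds)$informative[[endpoint]]
}
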