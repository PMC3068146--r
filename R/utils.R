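# Internal helpers: seeded evaluation, stratified resampling, log-space
# hypergeometric tails.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 32-bit seed from a master seed.
deriveSeed <- function(seed, stream) {
  s <- (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483629
  as.integer(s) + 1L
}

# Stratified assignment of samples to k folds; labels is a factor-like
# vector. Within each class, shuffled indices are dealt round-robin so fold
# sizes differ by at most one per class. Returns an integer fold id per
# sample. Uses the current RNG stream.
stratifiedFolds <- function(labels, k, stratified = TRUE) {
  n <- length(labels)
  if (k > n) stop("more folds than samples")
  fold <- integer(n)
  if (!stratified) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
    return(fold)
  }
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

# Stratified train/test split; returns logical train indicator.
stratifiedSplit <- function(labels, trainFraction, stratified = TRUE) {
  n <- length(labels)
  train <- logical(n)
  if (!stratified) {
    train[sample.int(n, max(1L, round(trainFraction * n)))] <- TRUE
    return(train)
  }
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    nTrain <- max(1L, round(trainFraction * length(idx)))
    nTrain <- min(nTrain, length(idx) - 1L)  # keep >= 1 test sample
    train[idx[sample.int(length(idx))][seq_len(nTrain)]] <- TRUE
  }
  train
}

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Natural-log right-tail hypergeometric probability P(X >= f) where X counts
# focus genes in a size-s draw from a universe of N genes containing G focus
# genes. Computed by summing log-binomial terms, stable for large N.
logHyperTail <- function(f, N, G, s) {
  upper <- min(G, s)
  if (f <= max(0L, s - (N - G))) return(0)  # tail covers the whole support
  if (f > upper) stop("f must not exceed min(G, s)")
  i <- f:upper
  terms <- lchoose(G, i) + lchoose(N - G, s - i) - lchoose(N, s)
  logSumExp(terms)
}

# Column index helper: accept gene ids or integer indices against a dataset.
resolveGenes <- function(ds, genes) {
  if (is.character(genes)) {
    idx <- match(genes, geneIds(ds))
    if (anyNA(idx))
      stop("unknown gene id(s): ",
           paste(genes[is.na(idx)], collapse = ", "))
    idx
  } else {
    idx <- as.integer(genes)
    if (any(idx < 1L) || any(idx > nrow(ds)))
      stop("gene index out of range")
    idx
  }
}

# samples x genes design matrix for a gene subset
designMatrix <- function(ds, genes) {
  idx <- resolveGenes(ds, genes)
  t(exprMatrix(ds)[idx, , drop = FALSE])
}

# Check that two ExprSets form a paired design: same patient set and equal
# per-patient endpoint labels.
checkPaired <- function(normal, tumour) {
  pn <- patientIds(normal); pt <- patientIds(tumour)
  if (!setequal(pn, pt))
    stop("datasets are not paired: patient sets differ")
  for (ep in intersect(endpointNames(normal), endpointNames(tumour))) {
    ln <- endpointLabels(normal, ep)[match(sort(pn), pn)]
    lt <- endpointLabels(tumour, ep)[match(sort(pn), pt)]
    if (!all(ln == lt))
      stop("datasets are not paired: endpoint '", ep,
           "' labels differ between compartments")
  }
  invisible(TRUE)
}
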