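#' Gene-signature selectors for the specificity test
#'
#' A selector is a function `(ds, endpoint) -> gene indices` applied to the
#' training portion of the signature tissue. `gaSelector()` runs a
#' reduced-budget GA search and returns its best chromosome;
#' `univariateSelector()` returns the top-k genes by two-class F ratio and
#' serves as a fast baseline.
#'
#' `gaRepresentativeSelector()` is the full representative-model procedure:
#' many short GA runs are pooled, genes are ranked by inclusion frequency in
#' the most predictive models, and a representative subset is distilled by
#' forward selection — planted signal recurs across independent runs while
#' run-specific overfit genes do not, so the frequency ranking is
#' considerably more stable than any single run's best chromosome. Selector
#' seeds are drawn from the ambient RNG stream, so callers control
#' reproducibility by seeding it.
#'
#' @param cfg a [GAConfig-class] (selection budget).
#' @param cv a [CVConfig-class] for the GA fitness level.
#' @return A selector function.
#' @export
gaSelector <- function(cfg = gaConfig(populationSize = 40L,
                                      generations = 25L, nRuns = 2L,
                                      goalAccuracy = 0.99),
                       cv = cvConfig()) {
  force(cfg); force(cv)
  function(ds, endpoint) {
    sd <- sample.int(2147483646L, 1L)
    cfg@seed <- sd
    cv@seed <- sd + 1L
    pop <- gaEvolve(ds, endpoint, cfg, cv)
    rec <- pop@records
    best <- rec[order(-rec$fitness, rec$genes), , drop = FALSE][1L, ]
    as.integer(strsplit(best$genes, ",")[[1L]])
  }
}

#' @rdname gaSelector
#' @param topFraction fraction of top-fitness models ranked by frequency.
#' @param maxSize,tolerance,patience forward-selection controls; the default
#'   tolerance (0.02) is commensurate with the fold-noise of the inner
#'   estimate so chance improvements are not banked.
#' @param forwardRepeats inner-CV repeats used during forward selection.
#' @export
gaRepresentativeSelector <- function(cfg = gaConfig(populationSize = 30L,
                                                    generations = 12L,
                                                    nRuns = 80L,
                                                    goalAccuracy = 0.99),
                                     cv = cvConfig(innerRepeats = 3L),
                                     topFraction = 0.05, maxSize = 10L,
                                     tolerance = 0.02, patience = 8L,
                                     forwardRepeats = 10L) {
  force(cfg); force(cv)
  function(ds, endpoint) {
    sd <- sample.int(2147483646L, 1L)
    cfg@seed <- sd
    cv@seed <- sd + 1L
    pop <- gaEvolve(ds, endpoint, cfg, cv)
    fr <- geneFrequency(pop, topFraction, geneIds(ds))
    rm <- forwardSelectRepresentative(
      fr$index, ds, endpoint,
      cvConfig(innerK = cv@innerK, innerRepeats = forwardRepeats,
               outerSplits = 1L, seed = sd + 2L),
      maxSize = maxSize, tolerance = tolerance, patience = patience)
    match(modelGenes(rm), geneIds(ds))
  }
}

#' @rdname gaSelector
#' @param k number of genes to keep.
#' @export
univariateSelector <- function(k = 5L) {
  force(k)
  function(ds, endpoint) {
    rk <- univariateRank(ds, endpoint)
    utils::head(rk$index, k)
  }
}

#' Tissue-specificity swap test for selected signatures
#'
#' Two-step protocol on paired normal/tumour data. Step 1: within the
#' signature tissue, split samples 2/3 training / 1/3 testing, run the
#' selector on the training set, fit the discriminant on the training set
#' restricted to the selected genes, and record held-out accuracy. Step 2:
#' carry the selected genes into the paired other tissue, split it with the
#' SAME patient partition (a patient's two samples are always co-assigned,
#' so no test patient leaks into either training set), retrain the
#' discriminant there from scratch, and record its held-out accuracy. Both
#' steps are repeated `nRepeats` times over fresh patient splits.
#'
#' A signature that is genuinely specific to its tissue keeps Step 1
#' accuracy high while Step 2 falls to chance; a signature reflecting shared
#' biology keeps both high.
#'
#' @param normal,tumour paired [ExprSet-class] objects (same patients).
#' @param endpoint endpoint name, present in both.
#' @param signatureTissue `"normal"` or `"tumour"`: where Step 1 selects.
#' @param selector function `(ds, endpoint) -> gene indices`; default the
#'   representative-model procedure [gaRepresentativeSelector()].
#' @param nRepeats number of repeated splits.
#' @param seed master seed; per-repeat split and selector seeds derive from
#'   it.
#' @param trainFraction training fraction of the patient split.
#' @return A [SpecificityResult-class].
#' @export
specificityTest <- function(normal, tumour, endpoint,
                            signatureTissue = "normal",
                            selector = gaRepresentativeSelector(),
                            nRepeats = 10L,
                            seed = 1L, trainFraction = 2 / 3) {
  checkPaired(normal, tumour)
  stopifnot(signatureTissue %in% c("normal", "tumour"))
  sigDs <- if (signatureTissue == "normal") normal else tumour
  othDs <- if (signatureTissue == "normal") tumour else normal

  same <- numeric(nRepeats)
  cross <- numeric(nRepeats)
  sigs <- vector("list", nRepeats)
  patients <- patientIds(sigDs)
  patLabels <- unname(endpointLabels(sigDs, endpoint))

  for (r in seq_len(nRepeats)) {
    trainPat <- withSeed(deriveSeed(seed, r),
                         stratifiedSplit(patLabels, trainFraction))
    trainPatients <- patients[trainPat]

    sigTrain <- sigDs[, patientIds(sigDs) %in% trainPatients]
    sigTest <- sigDs[, !patientIds(sigDs) %in% trainPatients]
    genes <- withSeed(deriveSeed(seed, 10000 + r),
                      selector(sigTrain, endpoint))
    sigs[[r]] <- geneIds(sigDs)[genes]

    fit1 <- fitMLHD(sigTrain, endpoint, genes)
    same[r] <- .accuracy(predictMLHD(fit1, sigTest)$labels,
                         endpointLabels(sigTest, endpoint))

    othTrain <- othDs[, patientIds(othDs) %in% trainPatients]
    othTest <- othDs[, !patientIds(othDs) %in% trainPatients]
    fit2 <- fitMLHD(othTrain, endpoint, genes)
    cross[r] <- .accuracy(predictMLHD(fit2, othTest)$labels,
                          endpointLabels(othTest, endpoint))
  }
  new("SpecificityResult", sameTissue = same, crossTissue = cross,
      endpoint = endpoint, signatureTissue = signatureTissue,
      signatures = sigs)
}

#' Write a specificity report TSV
#'
#' One row per (direction, repeat): tissue the model was tested in, whether
#' it was the signature tissue (`same`) or the swapped one (`cross`), and
#' the held-out accuracy.
#'
#' @param res a [SpecificityResult-class].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeSpecificityReport <- function(res, path) {
  n <- length(res@sameTissue)
  other <- setdiff(c("normal", "tumour"), res@signatureTissue)
  df <- data.frame(
    endpoint = res@endpoint,
    tissue = c(rep(res@signatureTissue, n), rep(other, n)),
    direction = rep(c("same", "cross"), each = n),
    repeat_index = c(seq_len(n), seq_len(n)),
    accuracy = c(res@sameTissue, res@crossTissue))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene contribution profiles by principal component analysis
#'
#' Decomposes the (per-gene mean-centred) expression of a signature gene set
#' into principal components and reports, per component, the unit-norm
#' loading of every gene, the fraction of total variance explained, and the
#' genes whose absolute loading exceeds `threshold` (default 0.3) — the
#' working definition of a gene contributing materially to the component.
#' Sign convention: each component is flipped, together with its sample
#' scores, so that its largest-magnitude loading is positive.
#'
#' Constant genes carry no direction and are dropped with a warning; fewer
#' than two non-constant genes is an error.
#'
#' @param ds an [ExprSet-class].
#' @param genes signature gene ids or indices (>= 2).
#' @param nComponents components to return (capped by rank).
#' @param threshold highlighting threshold on |loading|.
#' @return List with `profiles` (list of [LoadingProfile-class]) and
#'   `scores` (samples x components matrix of sample coordinates).
#' @export
pcaContributions <- function(ds, genes, nComponents = 2L, threshold = 0.3) {
  idx <- resolveGenes(ds, genes)
  if (length(idx) < 2L) stop("need at least two genes")
  X <- designMatrix(ds, idx)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant gene(s): ",
            paste(geneIds(ds)[idx[sds == 0]], collapse = ", "))
    idx <- idx[sds > 0]
    if (length(idx) < 2L)
      stop("fewer than two non-constant genes remain")
    X <- X[, sds > 0, drop = FALSE]
  }
  nComponents <- min(nComponents, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  totVar <- sum(pc$sdev^2)
  ids <- geneIds(ds)[idx]
  profiles <- vector("list", nComponents)
  scores <- pc$x[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(nComponents)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) {
      load <- -load
      scores[, j] <- -scores[, j]
    }
    names(load) <- ids
    profiles[[j]] <- new("LoadingProfile", componentIndex = j,
                         loadings = load,
                         explainedVariance = pc$sdev[j]^2 / totVar,
                         highlighted = ids[abs(load) > threshold])
  }
  list(profiles = profiles, scores = scores)
}

#' Write PCA loading profiles to TSV
#'
#' @param contrib result of [pcaContributions()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeLoadingReport <- function(contrib, path) {
  df <- do.call(rbind, lapply(contrib$profiles, function(p) data.frame(
    gene = names(p@loadings), component = p@componentIndex,
    loading = unname(p@loadings),
    explained_variance = p@explainedVariance,
    highlighted = names(p@loadings) %in% p@highlighted,
    stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
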