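#' Gene inclusion frequencies in the most predictive models
#'
#' Ranks genes by how often they appear in the top fraction (default the top
#' 1%) of a model population ordered by fitness. Models tied with the
#' boundary fitness are all included. Frequency ties are broken by gene id.
#'
#' @param pop a [ModelPopulation-class].
#' @param topFraction fraction of models to keep, in (0, 1\].
#' @param geneIdsUniverse optional character vector mapping indices to ids
#'   (defaults to `g<index>`).
#' @return data.frame with columns `gene` (id), `index`, `frequency`
#'   (fraction of kept models containing the gene), sorted by decreasing
#'   frequency.
#' @export
geneFrequency <- function(pop, topFraction = 0.01,
                          geneIdsUniverse = NULL) {
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must be in (0,1]")
  rec <- pop@records
  if (nrow(rec) == 0L) stop("empty model population")
  nTop <- ceiling(topFraction * nrow(rec))
  cutoff <- sort(rec$fitness, decreasing = TRUE)[nTop]
  keep <- rec[rec$fitness >= cutoff, , drop = FALSE]
  if (nrow(keep) == 0L) stop("empty top slice")
  geneLists <- strsplit(keep$genes, ",")
  counts <- table(as.integer(unlist(geneLists)))
  idx <- as.integer(names(counts))
  ids <- if (is.null(geneIdsUniverse)) paste0("g", idx)
         else geneIdsUniverse[idx]
  df <- data.frame(gene = ids, index = idx,
                   frequency = as.numeric(counts) / nrow(keep),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$frequency, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Forward-select a representative model from a ranked gene list
#'
#' Walks the ranked list (duplicates dropped), adding a gene only when it
#' improves the inner-CV accuracy by more than `tolerance` (default 0.001).
#' The walk stops when `maxSize` genes are kept or when `patience`
#' consecutive candidates fail to improve. The final model is scored with
#' both the inner-CV and the outer repeated-split estimators, since which of
#' the two a summary accuracy should quote is a reporting choice.
#'
#' @param rankedGenes gene ids or indices, best first (e.g. the `gene`
#'   column of [geneFrequency()]).
#' @param ds an [ExprSet-class].
#' @param endpoint endpoint name.
#' @param cv a [CVConfig-class].
#' @param maxSize maximum model size.
#' @param tolerance minimum strict accuracy improvement to keep a gene.
#' @param patience consecutive failed candidates before stopping.
#' @param method label stored in the result (default `"GA-MLHD"`).
#' @return A [RepresentativeModel-class].
#' @export
forwardSelectRepresentative <- function(rankedGenes, ds, endpoint,
                                        cv = cvConfig(), maxSize = 10L,
                                        tolerance = 0.001, patience = 5L,
                                        method = "GA-MLHD") {
  if (length(rankedGenes) == 0L) stop("ranked gene list must be non-empty")
  idx <- resolveGenes(ds, rankedGenes)
  idx <- idx[!duplicated(idx)]
  chosen <- integer()
  bestAcc <- 0
  fails <- 0L
  for (g in idx) {
    if (length(chosen) >= maxSize) break
    acc <- innerCVAccuracy(ds, endpoint, c(chosen, g), cv)
    if (acc > bestAcc + tolerance) {
      chosen <- c(chosen, g)
      bestAcc <- acc
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails >= patience) break
    }
  }
  if (length(chosen) == 0L) chosen <- idx[1L]  # never return an empty model
  inner <- innerCVAccuracy(ds, endpoint, chosen, cv)
  outer <- outerAccuracy(ds, endpoint, chosen, cv)$mean
  new("RepresentativeModel", genes = geneIds(ds)[chosen],
      method = method, endpoint = endpoint, tissue = tissueType(ds),
      accuracyInner = inner, accuracyOuter = outer,
      size = length(chosen))
}

#' Right-tail hypergeometric significance of a top-k gene-list overlap
#'
#' Probability of observing at least the given overlap between two random
#' gene lists of the stated sizes drawn from a common universe — the test
#' used to compare top-50 frequency-ranked gene lists across methods or
#' datasets.
#'
#' @param listA,listB character gene-id vectors.
#' @param universeSize size of the common gene universe.
#' @return List with `overlap`, `pValue`, `expected` (expected overlap under
#'   independence) and the input sizes.
#' @export
overlapSignificance <- function(listA, listB, universeSize) {
  a <- length(unique(listA))
  b <- length(unique(listB))
  if (universeSize < max(a, b))
    stop("universe smaller than a gene list")
  ov <- length(intersect(unique(listA), unique(listB)))
  if (ov > min(a, b)) stop("invalid input: overlap exceeds list length")
  p <- exp(logHyperTail(ov, universeSize, a, b))
  list(overlap = ov, pValue = min(p, 1), expected = a * b / universeSize,
       sizeA = a, sizeB = b, universe = universeSize)
}

#' Write representative models as a Table-1-shaped TSV
#'
#' One row per model: endpoint, tissue, method, accuracy (%, both
#' estimators), size and the comma-joined gene list.
#'
#' @param models list of [RepresentativeModel-class] objects.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeRepresentativeModels <- function(models, path) {
  df <- do.call(rbind, lapply(models, function(m) data.frame(
    endpoint = m@endpoint, tissue = m@tissue, method = m@method,
    accuracy_inner_pct = round(100 * m@accuracyInner, 1),
    accuracy_outer_pct = round(100 * m@accuracyOuter, 1),
    size = m@size, genes = paste(m@genes, collapse = ","),
    stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
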