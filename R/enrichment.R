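#' Hypergeometric network enrichment score
#'
#' For a universe of `N` genes containing `G` focus genes, and a pathway
#' (network) of `s` genes of which `f` are focus genes, the right-tail
#' probability of at least `f` focus genes arising by chance is
#' `p = sum_{i=f}^{min(G,s)} C(G,i) C(N-G,s-i) / C(N,s)`, and the score is
#' `-log10(p)`; the sum is evaluated in log space so large universes are
#' safe. A score above 5 is the conventional selection filter and is
#' equivalent to `p < 1e-5`.
#'
#' @param N universe size.
#' @param G number of focus genes in the universe.
#' @param s pathway size.
#' @param f focus genes in the pathway.
#' @return A [ScoredPathway-class].
#' @examples
#' networkScore(N = 1000, G = 40, s = 35, f = 12)
#' @export
networkScore <- function(N, G, s, f) {
  N <- as.integer(N); G <- as.integer(G)
  s <- as.integer(s); f <- as.integer(f)
  if (G > N || s > N) stop("invalid input: G and s must not exceed N")
  if (f > min(G, s)) stop("invalid input: f must not exceed min(G, s)")
  if (f < 0) stop("invalid input: f must be non-negative")
  logp <- logHyperTail(f, N, G, s)
  p <- min(exp(logp), 1)
  new("ScoredPathway", N = N, G = G, s = s, f = f, pRight = p,
      score = -logp / log(10))
}

#' Score user-supplied gene sets against a focus-gene list
#'
#' Applies [networkScore()] to every gene set: `s` is the number of set
#' genes present in the universe, `f` the number that are focus genes.
#'
#' @param focusGenes character focus gene ids (e.g. a model population's
#'   gene list).
#' @param geneSets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of all assayed gene ids.
#' @return data.frame with one row per set: `set`, `N`, `G`, `s`, `f`, `p`,
#'   `score`, `pass_score_gt_5`.
#' @export
scoreGeneSets <- function(focusGenes, geneSets, universe) {
  universe <- unique(universe)
  focus <- intersect(unique(focusGenes), universe)
  N <- length(universe)
  G <- length(focus)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(geneSets[[nm]]), universe)
    f <- length(intersect(set, focus))
    sp <- networkScore(N, G, length(set), f)
    data.frame(set = nm, N = N, G = G, s = length(set), f = f,
               p = sp@pRight, score = sp@score,
               pass_score_gt_5 = sp@score > 5,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$score, out$set), , drop = FALSE]
}

#' Right-tailed Fisher exact test for pathway enrichment
#'
#' Exact right-tail probability for a 2x2 contingency table (delegated to
#' [stats::fisher.test] with `alternative = "greater"`); the conventional
#' canonical-pathway significance filter is `p < 0.01`.
#'
#' @param table 2x2 matrix of non-negative integer counts, with the
#'   focus-and-in-pathway cell at position \[1,1\].
#' @param alpha significance level for the `significant` flag.
#' @return List with `pValue` and `significant`.
#' @export
fisherPathwayTest <- function(table, alpha = 0.01) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("cells must be non-negative")
  if (any(table != round(table))) stop("cells must be integers")
  p <- stats::fisher.test(table, alternative = "greater")$p.value
  list(pValue = p, significant = p < alpha)
}

#' One-factor ANOVA across sample groups for a single gene
#'
#' Classic one-way fixed-effects ANOVA of one gene's expression across
#' labelled sample groups (e.g. the epithelial-cell populations of a
#' tumour-progression series), returning the group means, F statistic and
#' p-value.
#'
#' @param ds an [ExprSet-class].
#' @param gene gene id or index.
#' @param groupLabels character/factor of group labels, one per sample.
#' @return List with `gene`, `groupMeans`, `F`, `pValue`.
#' @export
anovaByGroup <- function(ds, gene, groupLabels) {
  idx <- resolveGenes(ds, gene)
  if (length(idx) != 1L) stop("one gene at a time")
  y <- as.numeric(exprMatrix(ds)[idx, ])
  g <- factor(groupLabels)
  tab <- table(g)
  if (length(tab) < 2L) stop("need at least two groups")
  small <- names(tab)[tab < 2L]
  if (length(small))
    stop("group '", small[1L], "' has fewer than 2 samples")
  fit <- stats::anova(stats::lm(y ~ g))
  list(gene = geneIds(ds)[idx],
       groupMeans = tapply(y, g, mean),
       F = fit[["F value"]][1L],
       pValue = fit[["Pr(>F)"]][1L])
}

#' Univariate F-ratio ranking of genes for a binary endpoint
#'
#' The univariate baseline: every gene scored by its two-class F ratio
#' (between-group over within-group mean square; for two classes this equals
#' the squared pooled two-sample t statistic), with the matching two-sided
#' t-test p-value and its Benjamini-Hochberg adjustment for reference.
#' Constant genes get F = 0 and rank last; remaining ties break by gene id.
#'
#' @param ds an [ExprSet-class].
#' @param endpoint binary endpoint name.
#' @return data.frame sorted by decreasing F: `gene`, `index`, `F`,
#'   `t`, `p_value`, `fdr`.
#' @export
univariateRank <- function(ds, endpoint) {
  y <- unname(endpointLabels(ds, endpoint))
  if (length(unique(y)) != 2L) stop("endpoint must be binary")
  m <- exprMatrix(ds)
  i0 <- y == 0L
  i1 <- y == 1L
  n0 <- sum(i0); n1 <- sum(i1)
  m0 <- rowMeans(m[, i0, drop = FALSE])
  m1 <- rowMeans(m[, i1, drop = FALSE])
  ss0 <- rowSums((m[, i0, drop = FALSE] - m0)^2)
  ss1 <- rowSums((m[, i1, drop = FALSE] - m1)^2)
  sp2 <- (ss0 + ss1) / (n0 + n1 - 2L)
  tstat <- ifelse(sp2 > 0, (m1 - m0) / sqrt(sp2 * (1 / n0 + 1 / n1)), 0)
  Fstat <- tstat^2
  pv <- ifelse(sp2 > 0,
               2 * stats::pt(abs(tstat), df = n0 + n1 - 2L,
                             lower.tail = FALSE), 1)
  df <- data.frame(gene = rownames(m), index = seq_len(nrow(m)),
                   F = Fstat, t = tstat, p_value = pv,
                   fdr = stats::p.adjust(pv, method = "BH"),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$F, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}
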