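#' Inner k-fold cross-validated discriminant accuracy
#'
#' The first level of the two-level error-estimation scheme: the accuracy of
#' a fixed gene subset estimated by stratified k-fold cross-validation
#' (default k = 5). This is the fitness the genetic algorithm maximises
#' during evolution. The returned value is the mean over folds of the
#' fraction of correct test-fold predictions; fold construction is
#' deterministic given `cv@seed`. `innerK = n` reproduces leave-one-out.
#'
#' If a stratified split still leaves a training fold without one of the
#' classes (possible for very small classes), the split is redrawn once
#' before failing.
#'
#' @param ds an [ExprSet-class].
#' @param endpoint endpoint name.
#' @param genes gene ids or indices.
#' @param cv a [CVConfig-class].
#' @param priors passed to the discriminant fit.
#' @return Accuracy in \[0, 1\].
#' @export
innerCVAccuracy <- function(ds, endpoint, genes, cv = cvConfig(),
                            priors = "empirical") {
  X <- designMatrix(ds, genes)
  y <- unname(endpointLabels(ds, endpoint))
  if (nrow(X) < cv@innerK) stop("fewer samples than inner folds")
  withSeed(cv@seed, {
    if (length(unique(y)) == 2L && identical(priors, "empirical")) {
      # two-class path goes through the compiled evaluator
      foldsMat <- do.call(cbind, lapply(seq_len(cv@innerRepeats),
        function(r) .foldsWithAllClasses(y, cv@innerK, cv@stratified)))
      .cppBatchCV(X, match(y, sort(unique(y))) - 1L, foldsMat,
                  list(seq_len(ncol(X))))[1L]
    } else {
      mean(vapply(seq_len(cv@innerRepeats), function(r)
        .innerCVMatrix(X, y, cv@innerK, cv@stratified, priors), numeric(1)))
    }
  })
}

# Matrix-level inner CV using the current RNG stream.
.innerCVMatrix <- function(X, y, k, stratified = TRUE,
                           priors = "empirical") {
  folds <- .foldsWithAllClasses(y, k, stratified)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- .fitMLHDMatrix(X[!test, , drop = FALSE], y[!test],
                          priors = priors)
    pred <- predictMLHD(fit, X[test, , drop = FALSE])$labels
    accs[f] <- .accuracy(pred, y[test])
  }
  mean(accs)
}

.foldsWithAllClasses <- function(y, k, stratified) {
  for (attempt in 1:2) {
    folds <- stratifiedFolds(y, k, stratified)
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds != f])) == length(unique(y)), logical(1)))
    if (ok) return(folds)
  }
  stop("a class is absent from a training fold; too few samples per class")
}

#' Outer repeated-random-split accuracy
#'
#' The second level of the error-estimation scheme: after selection is
#' finished, the accuracy of a gene subset is estimated as the average test
#' error over repeated stratified random splits of the entire dataset
#' (default 40 splits, 2/3 training / 1/3 testing).
#'
#' @inheritParams innerCVAccuracy
#' @return List with `mean` and `perSplit` (numeric vector of length
#'   `cv@outerSplits`).
#' @export
outerAccuracy <- function(ds, endpoint, genes, cv = cvConfig(),
                          priors = "empirical") {
  X <- designMatrix(ds, genes)
  y <- unname(endpointLabels(ds, endpoint))
  withSeed(cv@seed, {
    per <- vapply(seq_len(cv@outerSplits), function(s) {
      train <- stratifiedSplit(y, cv@trainFraction, cv@stratified)
      fit <- .fitMLHDMatrix(X[train, , drop = FALSE], y[train],
                            priors = priors)
      pred <- predictMLHD(fit, X[!train, , drop = FALSE])$labels
      .accuracy(pred, y[!train])
    }, numeric(1))
    list(mean = mean(per), perSplit = per)
  })
}

#' Write per-split accuracies to a TSV report
#'
#' @param outer result of [outerAccuracy()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeAccuracyReport <- function(outer, path) {
  df <- data.frame(split = seq_along(outer$perSplit),
                   accuracy = outer$perSplit)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
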