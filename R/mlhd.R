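#' Fit a maximum-likelihood discriminant on a gene subset
#'
#' Gaussian discriminant analysis with class mean vectors and a single
#' within-class covariance matrix pooled over classes (denominator
#' `n - n_classes`). When the pooled covariance is numerically singular a
#' ridge of `eps * trace(S) / p` is added to the diagonal, with `eps`
#' starting at 1e-6 and escalating tenfold until the matrix factorises; the
#' amount actually added is stored in the model. Class priors default to the
#' empirical training frequencies; `priors = "equal"` uses 1/n_classes
#' (which of the two the original discriminant used is not documented, so
#' both are exposed).
#'
#' @param ds an [ExprSet-class].
#' @param endpoint endpoint name whose binary labels define the classes.
#' @param genes gene ids or 1-based indices; must be non-empty and unique.
#' @param priors `"empirical"` or `"equal"`.
#' @return An [MLHDModel-class].
#' @examples
#' pair <- generatePaired(syntheticConfig(nPatients = 20, nGenes = 30,
#'                                        nInformative = 5, effectSize = 2,
#'                                        seed = 3))
#' info <- S4Vectors::metadata(pair$normal)$informative$gleason
#' fit <- fitMLHD(pair$normal, "gleason", info)
#' fit
#' @export
fitMLHD <- function(ds, endpoint, genes, priors = c("empirical", "equal")) {
  priors <- match.arg(priors)
  idx <- resolveGenes(ds, genes)
  if (length(idx) == 0L) stop("gene subset must be non-empty")
  if (anyDuplicated(idx)) stop("invalid subset: duplicate gene index")
  X <- designMatrix(ds, idx)
  y <- endpointLabels(ds, endpoint)
  .fitMLHDMatrix(X, y, priors = priors,
                 geneIdx = idx, geneIds = geneIds(ds)[idx])
}

# Core fit on a samples x genes matrix; used directly by the CV loops.
.fitMLHDMatrix <- function(X, y, priors = "empirical",
                           geneIdx = seq_len(ncol(X)),
                           geneIds = as.character(geneIdx)) {
  classes <- sort(unique(y))
  if (length(classes) < 2L) stop("need at least two classes to fit")
  counts <- vapply(classes, function(cl) sum(y == cl), integer(1))
  if (any(counts < 2L))
    stop("each class needs >= 2 samples to fit (class ",
         classes[which(counts < 2L)[1L]], " has ",
         min(counts), ")")
  p <- ncol(X)
  n <- nrow(X)
  mu <- matrix(0, length(classes), p)
  S <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    mu[i, ] <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, mu[i, ])
    S <- S + crossprod(Xc)
  }
  S <- S / (n - length(classes))
  # ridge escalation until the covariance factorises
  ridge <- 0
  Sr <- S
  ok <- !inherits(try(chol(Sr), silent = TRUE), "try-error")
  if (!ok) {
    base <- sum(diag(S)) / p
    if (base <= 0) base <- 1
    eps <- 1e-6
    for (i in 1:24) {
      ridge <- eps * base
      Sr <- S + diag(ridge, p)
      if (!inherits(try(chol(Sr), silent = TRUE), "try-error")) {
        ok <- TRUE
        break
      }
      eps <- eps * 10
    }
    if (!ok) stop("pooled covariance could not be regularised")
  }
  pri <- if (identical(priors, "equal")) {
    rep(1 / length(classes), length(classes))
  } else {
    counts / n
  }
  names(pri) <- as.character(classes)
  new("MLHDModel", genes = as.integer(geneIdx),
      geneIds = as.character(geneIds), classes = as.character(classes),
      classMeans = mu, pooledCov = Sr, priors = pri, ridge = ridge)
}

#' Predict with a fitted discriminant
#'
#' Evaluates the linear discriminant score
#' `delta_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log prior_c` for every
#' class and assigns each sample to the maximising class; exact ties go to
#' the lowest class index.
#'
#' @param model an [MLHDModel-class].
#' @param newdata numeric matrix, samples x genes, with exactly
#'   `length(model@genes)` columns in the model's gene order, or an
#'   [ExprSet-class] from which the model genes are extracted.
#' @return List with `labels` (character class per sample) and `scores`
#'   (samples x classes discriminant score matrix).
#' @export
predictMLHD <- function(model, newdata) {
  if (is(newdata, "ExprSet")) newdata <- designMatrix(newdata, model@genes)
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(model@genes))
    stop("dimension mismatch: model has ", length(model@genes),
         " genes but newdata has ", ncol(newdata), " columns")
  R <- chol(model@pooledCov)
  # W = S^-1 mu_c' per class; const_c = -mu' S^-1 mu / 2 + log prior
  Minv <- backsolve(R, forwardsolve(t(R), t(model@classMeans)))
  const <- -0.5 * colSums(t(model@classMeans) * Minv) + log(model@priors)
  scores <- newdata %*% Minv
  scores <- sweep(scores, 2L, const, "+")
  colnames(scores) <- model@classes
  rownames(scores) <- rownames(newdata)
  labels <- model@classes[max.col(scores, ties.method = "first")]
  list(labels = labels, scores = scores)
}

.accuracy <- function(pred, truth) mean(pred == as.character(truth))
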