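# Independent oracles: brute-force discriminant, numeric integration of the
# probit marginal likelihood, exact big-integer hypergeometric tails (via
# the system Python's rational arithmetic), and a direct eigendecomposition.

# Brute-force pooled-covariance Gaussian discriminant: evaluates the full
# quadratic log-density -(x-mu)' S^-1 (x-mu)/2 + log prior per class with
# solve(), a different route from the package's linear-score formulation.
bruteDiscriminantPredict <- function(Xtr, ytr, Xte) {
  classes <- sort(unique(ytr))
  n <- nrow(Xtr)
  mus <- lapply(classes, function(cl)
    colMeans(Xtr[ytr == cl, , drop = FALSE]))
  S <- matrix(0, ncol(Xtr), ncol(Xtr))
  for (i in seq_along(classes)) {
    Xc <- sweep(Xtr[ytr == classes[i], , drop = FALSE], 2, mus[[i]])
    S <- S + crossprod(Xc)
  }
  S <- S / (n - length(classes))
  Sinv <- solve(S)
  priors <- vapply(classes, function(cl) mean(ytr == cl), numeric(1))
  apply(Xte, 1, function(x) {
    dens <- vapply(seq_along(classes), function(i) {
      d <- x - mus[[i]]
      -0.5 * drop(t(d) %*% Sinv %*% d) + log(priors[i])
    }, numeric(1))
    classes[which.max(dens)]
  })
}

# Numeric integration of the probit marginal likelihood p(z | gamma):
# integral over beta (dim <= 3) of N(z; A beta, I) N(beta; 0, c I), on a
# Simpson grid centred at the posterior mean and spanning +/- 10 posterior
# standard deviations per dimension.
numericLogMarginal <- function(A, z, priorScale, m = 81L) {
  k <- ncol(A)
  stopifnot(k <= 3L)
  V <- solve(crossprod(A) + diag(1 / priorScale, k))
  bhat <- drop(V %*% crossprod(A, z))
  sds <- sqrt(diag(V))
  axes <- lapply(seq_len(k), function(j)
    seq(bhat[j] - 10 * sds[j], bhat[j] + 10 * sds[j], length.out = m))
  # Simpson weights (m odd)
  w1 <- c(1, rep(c(4, 2), length.out = m - 2L), 1)
  grid <- as.matrix(expand.grid(axes))
  wts <- Reduce(function(a, b) outer(a, b), rep(list(w1), k))
  h <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  logf <- apply(grid, 1, function(b) {
    r <- z - drop(A %*% b)
    -length(z) / 2 * log(2 * pi) - 0.5 * sum(r^2) -
      k / 2 * log(2 * pi * priorScale) - sum(b^2) / (2 * priorScale)
  })
  lw <- log(as.vector(wts)) + sum(log(h / 3))
  mx <- max(logf + lw)
  mx + log(sum(exp(logf + lw - mx)))
}

# Exact rational hypergeometric right tail using Python's big integers.
pythonBin <- local({
  found <- NULL
  function() {
    if (is.null(found)) {
      for (cand in c("python3", "python")) {
        p <- Sys.which(cand)
        if (nzchar(p)) { found <<- p; break }
      }
      if (is.null(found)) stop("no python interpreter found")
    }
    found
  }
})

exactHyperTail <- function(f, N, G, s) {
  code <- sprintf(paste0(
    "from fractions import Fraction\nfrom math import comb\n",
    "f,N,G,s=%d,%d,%d,%d\n",
    "p=sum(Fraction(comb(G,i)*comb(N-G,s-i),comb(N,s))",
    " for i in range(f,min(G,s)+1))\n",
    "print(repr(float(p)))"), f, N, G, s)
  out <- system2(pythonBin(), "-", input = code, stdout = TRUE)
  as.numeric(out[length(out)])
}

# Direct eigendecomposition of the sample covariance (PCA oracle).
eigenLoadings <- function(X) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  list(values = ev$values, vectors = ev$vectors)
}
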