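# Bayesian variable selection for a binary probit model.
#
# Latent formulation: z_i ~ N(x_i' beta, 1), y_i = 1{z_i > 0}. Given an
# inclusion vector gamma, the design holds an always-included intercept plus
# the gamma-selected (standardised) gene columns, and beta | gamma is
# N(0, c I). beta is integrated out analytically in the Metropolis-Hastings
# ratio for gamma; z is refreshed by Gibbs from sign-truncated normals; beta
# itself is refreshed from its Gaussian full conditional.

# log p(z | gamma) with beta integrated out: z ~ N(0, I + c A A') where A is
# the n x k design for gamma (intercept included). Uses the determinant
# lemma and Woodbury so only a k x k factorisation is needed.
.bvsLogMarginalMatrix <- function(A, z, priorScale) {
  n <- length(z)
  k <- ncol(A)
  if (k == 0L)
    return(-n / 2 * log(2 * pi) - 0.5 * sum(z^2))
  Vinv <- crossprod(A) + diag(1 / priorScale, k)
  R <- chol(Vinv)
  logDetS <- k * log(priorScale) + 2 * sum(log(diag(R)))
  Atz <- crossprod(A, z)
  w <- backsolve(R, forwardsolve(t(R), Atz))
  quad <- sum(z^2) - sum(Atz * w)
  -n / 2 * log(2 * pi) - 0.5 * logDetS - 0.5 * quad
}

#' Log marginal likelihood of the latent vector under an inclusion set
#'
#' Computes `log p(z | gamma)` for the probit latent vector `z` with the
#' gene coefficients integrated out under their independent `N(0, c)` prior;
#' an intercept column of ones is always included. Exposed so the analytic
#' integration can be checked against direct numeric integration over the
#' coefficients.
#'
#' @param X standardised samples x genes matrix.
#' @param z latent vector (one value per sample).
#' @param gamma integer indices of included genes (possibly empty).
#' @param priorScale coefficient prior variance c.
#' @return Scalar log density.
#' @export
bvsLogMarginal <- function(X, z, gamma, priorScale = 10) {
  A <- cbind(1, X[, gamma, drop = FALSE])
  .bvsLogMarginalMatrix(A, z, priorScale)
}

# inverse-CDF truncated standard-width normal sampler: N(mean, 1) truncated
# to (0, Inf) if positive else (-Inf, 0)
.rtruncnorm <- function(mean, positive) {
  lo <- ifelse(positive, 0, -Inf)
  hi <- ifelse(positive, Inf, 0)
  pLo <- pnorm(lo, mean, 1)
  pHi <- pnorm(hi, mean, 1)
  u <- pLo + runif(length(mean)) * (pHi - pLo)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qnorm(u, mean, 1)
}

#' Run one BVS MCMC chain
#'
#' Alternates (a) a Gibbs refresh of the probit latent variables from
#' sign-truncated normals around the current linear predictor, (b) a Gibbs
#' refresh of the included coefficients from their Gaussian full
#' conditional, and (c) a Metropolis-Hastings add/delete/swap move on the
#' inclusion vector accepted by the ratio of marginal likelihoods (with
#' coefficients integrated out analytically) times the Bernoulli inclusion
#' prior, whose rate `expectedModelSize / nGenes` calibrates the prior mean
#' model size. Gene columns are standardised to mean 0, unit variance before
#' sampling.
#'
#' @param ds an [ExprSet-class].
#' @param endpoint a binary endpoint name.
#' @param cfg a [BVSConfig-class].
#' @param chainSeed seed for this chain (default derived from `cfg@seed`).
#' @return A [ChainSummary-class].
#' @export
bvsChain <- function(ds, endpoint, cfg = bvsConfig(), chainSeed = NULL) {
  validObject(cfg)
  y <- unname(endpointLabels(ds, endpoint))
  if (length(unique(y)) != 2L)
    stop("unsupported endpoint: BVS requires a binary endpoint with both ",
         "classes present")
  if (length(y) < 4L) stop("need at least 4 samples")
  X <- scale(designMatrix(ds, seq_len(nrow(ds))))
  X[is.nan(X)] <- 0  # constant genes carry no information
  nGenes <- ncol(X)
  w <- cfg@expectedModelSize / nGenes  # Bernoulli inclusion rate
  logPriorOdds <- log(w) - log(1 - w)
  if (is.null(chainSeed)) chainSeed <- cfg@seed

  withSeed(chainSeed, {
    gamma <- which(runif(nGenes) < w)
    if (length(gamma) == 0L) gamma <- sample.int(nGenes, 1L)
    z <- .rtruncnorm(rep(0, length(y)), y == 1L)
    kept <- cfg@nIterations - cfg@burnIn
    visits <- new.env(parent = emptyenv())
    incl <- numeric(nGenes)
    traceIt <- integer(kept)
    traceSize <- integer(kept)
    traceLm <- numeric(kept)
    ti <- 0L

    A <- cbind(1, X[, gamma, drop = FALSE])
    logM <- .bvsLogMarginalMatrix(A, z, cfg@priorScale)

    for (it in seq_len(cfg@nIterations)) {
      # (b) beta | z, gamma
      k <- ncol(A)
      Vinv <- crossprod(A) + diag(1 / cfg@priorScale, k)
      R <- chol(Vinv)
      betaHat <- backsolve(R, forwardsolve(t(R), crossprod(A, z)))
      beta <- betaHat + backsolve(R, rnorm(k))
      # (a) z | beta
      eta <- drop(A %*% beta)
      z <- .rtruncnorm(eta, y == 1L)
      logM <- .bvsLogMarginalMatrix(A, z, cfg@priorScale)

      # (c) MH moves on gamma: several per sweep for faster exploration
      for (mv in seq_len(cfg@nGammaMoves)) {
        move <- sample.int(3L, 1L, prob = cfg@moveProbs)
        prop <- gamma
        dPrior <- 0
        dHastings <- 0
        ok <- TRUE
        if (move == 1L) {            # add
          out <- setdiff(seq_len(nGenes), gamma)
          if (length(out)) {
            prop <- c(gamma, out[sample.int(length(out), 1L)])
            dPrior <- logPriorOdds
            # forward picks 1 of |out| to add; reverse picks 1 of k+1 to
            # delete
            dHastings <- log(length(out)) - log(length(gamma) + 1L)
          } else ok <- FALSE
        } else if (move == 2L) {     # delete
          if (length(gamma)) {
            prop <- gamma[-sample.int(length(gamma), 1L)]
            dPrior <- -logPriorOdds
            dHastings <- log(length(gamma)) -
              log(nGenes - length(gamma) + 1L)
          } else ok <- FALSE
        } else {                     # swap (symmetric proposal)
          out <- setdiff(seq_len(nGenes), gamma)
          if (length(gamma) && length(out)) {
            prop <- c(gamma[-sample.int(length(gamma), 1L)],
                      out[sample.int(length(out), 1L)])
          } else ok <- FALSE
        }
        if (ok) {
          Aprop <- cbind(1, X[, prop, drop = FALSE])
          logMProp <- .bvsLogMarginalMatrix(Aprop, z, cfg@priorScale)
          if (log(runif(1)) <= logMProp - logM + dPrior + dHastings) {
            gamma <- prop
            A <- Aprop
            logM <- logMProp
          }
        }
      }

      if (it > cfg@burnIn) {
        ti <- ti + 1L
        key <- paste0("s:", paste(sort(gamma), collapse = ","))
        visits[[key]] <- (visits[[key]] %||% 0L) + 1L
        incl[gamma] <- incl[gamma] + 1
        traceIt[ti] <- it
        traceSize[ti] <- length(gamma)
        traceLm[ti] <- logM
      }
    }
    keys <- ls(visits)
    vs <- data.frame(
      subset = sub("^s:", "", keys),
      visits = vapply(keys, function(k) visits[[k]], integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    vs <- vs[order(-vs$visits, vs$subset), , drop = FALSE]
    rownames(vs) <- NULL
    new("ChainSummary", visitedSubsets = vs,
        marginalInclusion = stats::setNames(incl / kept, geneIds(ds)),
        trace = data.frame(iteration = traceIt, size = traceSize,
                           log_marginal = traceLm),
        nIterations = cfg@nIterations, burnIn = cfg@burnIn)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic EM-style estimate of the Bayes probit coefficients for a
# fixed gene subset (ridge 1/c): iterates E[z | beta] over truncated normals
# and the Gaussian posterior mean for beta. Used to score candidate subsets.
.probitEMCoef <- function(A, y, priorScale, iters = 50L) {
  k <- ncol(A)
  Vinv <- crossprod(A) + diag(1 / priorScale, k)
  R <- chol(Vinv)
  beta <- rep(0, k)
  for (i in seq_len(iters)) {
    eta <- drop(A %*% beta)
    # truncated-normal mean: eta + sign * dnorm/(tail prob)
    d <- stats::dnorm(eta)
    pPos <- pnorm(eta)
    ez <- ifelse(y == 1L, eta + d / pmax(pPos, 1e-12),
                 eta - d / pmax(1 - pPos, 1e-12))
    beta <- backsolve(R, forwardsolve(t(R), crossprod(A, ez)))
  }
  drop(beta)
}

# Cross-validated misclassification error of a gene subset under the probit
# predictive rule (sign of the linear predictor); folds are shared across
# candidates so the comparison is paired and order-independent.
.probitCVError <- function(X, y, genes, priorScale, folds) {
  k <- max(folds)
  err <- 0L
  for (f in seq_len(k)) {
    test <- folds == f
    A <- cbind(1, X[!test, genes, drop = FALSE])
    beta <- .probitEMCoef(A, y[!test], priorScale)
    eta <- drop(cbind(1, X[test, genes, drop = FALSE]) %*% beta)
    err <- err + sum((eta > 0) != (y[test] == 1L))
  }
  err / length(y)
}

#' Pool BVS chains into a representative model
#'
#' Takes the union of the most frequently visited subsets across chains,
#' scores each candidate by cross-validated misclassification error under
#' the probit predictive rule (posterior-mode coefficients refit inside each
#' training fold), and returns the minimum-error candidate. Ties are broken
#' by smaller subset, then by higher total visit count, so the result does
#' not depend on chain order.
#'
#' @param summaries list of [ChainSummary-class] objects.
#' @param ds the [ExprSet-class] the chains were run on.
#' @param endpoint endpoint name.
#' @param nCandidates number of top-visited subsets per chain to score.
#' @param priorScale coefficient prior variance used in refits.
#' @param cvFolds folds for the error estimate.
#' @param seed RNG seed for the CV folds.
#' @return A [RepresentativeModel-class] with method `"BVS"`.
#' @export
poolChains <- function(summaries, ds, endpoint, nCandidates = 10L,
                       priorScale = 10, cvFolds = 5L, seed = 1L) {
  if (length(summaries) == 0L) stop("need at least one chain")
  tallies <- list()
  for (s in summaries) {
    vs <- visitedSubsets(s)
    if (nrow(vs) == 0L) stop("empty visit record in a chain")
    top <- utils::head(vs, nCandidates)
    for (i in seq_len(nrow(top))) {
      key <- top$subset[i]
      tallies[[key]] <- (tallies[[key]] %||% 0L) + top$visits[i]
    }
  }
  keys <- names(tallies)
  keys <- keys[keys != ""]  # the null model cannot classify
  if (length(keys) == 0L) stop("no non-empty candidate subsets")
  visits <- vapply(keys, function(k) tallies[[k]], numeric(1))
  X <- scale(designMatrix(ds, seq_len(nrow(ds))))
  X[is.nan(X)] <- 0
  y <- unname(endpointLabels(ds, endpoint))
  folds <- withSeed(seed, .foldsWithAllClasses(y, cvFolds, TRUE))
  errs <- vapply(keys, function(k) {
    genes <- as.integer(strsplit(k, ",")[[1L]])
    .probitCVError(X, y, genes, priorScale, folds)
  }, numeric(1))
  sizes <- vapply(strsplit(keys, ","), length, integer(1))
  ord <- order(errs, sizes, -visits, keys)
  best <- ord[1L]
  genes <- as.integer(strsplit(keys[best], ",")[[1L]])
  new("RepresentativeModel", genes = geneIds(ds)[genes], method = "BVS",
      endpoint = endpoint, tissue = tissueType(ds),
      accuracyInner = 1 - errs[best], accuracyOuter = NA_real_,
      size = length(genes))
}

#' Write a chain trace and subset report to TSV
#'
#' @param summary a [ChainSummary-class].
#' @param tracePath,subsetPath output files (NULL to skip either).
#' @return Invisibly, the paths written.
#' @export
writeChainSummary <- function(summary, tracePath = NULL,
                              subsetPath = NULL) {
  if (!is.null(tracePath))
    write.table(summary@trace, tracePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(subsetPath))
    write.table(visitedSubsets(summary), subsetPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(c(trace = tracePath, subsets = subsetPath))
}
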