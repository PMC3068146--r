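#' @import methods
#' @useDynLib TissueSig, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats rnorm runif pnorm qnorm var sd prcomp lm anova
#'   fisher.test pf pt p.adjust setNames quantile
#' @importFrom utils head read.delim write.table packageVersion
NULL

#' ExprSet: single-tissue expression dataset with endpoint labels
#'
#' An `ExprSet` holds a genes-by-samples expression matrix for one tissue
#' compartment (normal or tumour), together with per-sample patient
#' identifiers and one or more binary endpoint labels (e.g. Gleason-score
#' class, capsular penetration). It extends
#' [SummarizedExperiment::SummarizedExperiment]: the expression values live in
#' the `"exprs"` assay, sample annotations in `colData`, and the vector of
#' endpoint column names in `metadata(x)$endpoints`.
#'
#' Validity requirements: a numeric assay with no missing values, unique gene
#' and sample identifiers, a single tissue tag (`"normal"` or `"tumour"`)
#' shared by all samples, a `patient_id` column, and every declared endpoint
#' present in `colData` with values in \{0, 1\}.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment] for inherited
#'   slots; `ExprSet` adds none.
#' @seealso [ExprSet()] (constructor), [generatePaired()], [readDataset()]
#' @export
setClass("ExprSet", contains = "SummarizedExperiment")

.validExprSet <- function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is missing")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msg <- c(msg, "expression values must be numeric")
    else if (anyNA(m)) msg <- c(msg, "expression values contain NA")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!"tissue" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'tissue' column")
  else {
    tis <- unique(as.character(cd$tissue))
    if (length(tis) != 1L || !tis %in% c("normal", "tumour"))
      msg <- c(msg, "tissue must be a single value in {normal, tumour}")
  }
  if (!"patient_id" %in% colnames(cd))
    msg <- c(msg, "colData must contain a 'patient_id' column")
  eps <- S4Vectors::metadata(object)$endpoints
  for (ep in eps) {
    if (!ep %in% colnames(cd)) {
      msg <- c(msg, sprintf("declared endpoint '%s' missing from colData", ep))
    } else if (!all(cd[[ep]] %in% c(0L, 1L))) {
      msg <- c(msg, sprintf("endpoint '%s' must be binary 0/1", ep))
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ExprSet", .validExprSet)

#' Construct an ExprSet
#'
#' @param exprs numeric matrix, genes in rows and samples in columns, with
#'   row and column names.
#' @param tissue `"normal"` or `"tumour"`; one tag for the whole object.
#' @param patientId character vector of per-sample patient identifiers.
#' @param labels named list of binary (0/1) per-sample label vectors, one
#'   entry per endpoint.
#' @return A validated [ExprSet-class] object.
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' es <- ExprSet(m, tissue = "normal", patientId = paste0("P", 1:5),
#'               labels = list(gleason = c(0, 1, 0, 1, 1)))
#' es
#' @export
ExprSet <- function(exprs, tissue, patientId,
                    labels = list()) {
  stopifnot(is.matrix(exprs))
  cd <- S4Vectors::DataFrame(
    sample_id = colnames(exprs),
    patient_id = as.character(patientId),
    tissue = rep(as.character(tissue), ncol(exprs)),
    row.names = colnames(exprs)
  )
  for (ep in names(labels)) cd[[ep]] <- as.integer(labels[[ep]])
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd,
    metadata = list(endpoints = names(labels))
  )
  new("ExprSet", se)
}

#' Cross-validation configuration
#'
#' Parameters of the two-level error-estimation scheme: an inner k-fold
#' cross-validation (default `innerK = 5`) used as the selection fitness, and
#' an outer estimate averaged over repeated random splits (default 40 splits,
#' 2/3 training and 1/3 testing). Splits are stratified by class unless
#' `stratified = FALSE`.
#'
#' @slot innerK integer, number of inner folds (>= 2).
#' @slot innerRepeats integer >= 1, number of independent fold partitions
#'   averaged in the inner estimate (repeated k-fold; 1 = plain k-fold).
#' @slot outerSplits integer, number of outer random splits (>= 1).
#' @slot trainFraction numeric in (0,1), outer training fraction.
#' @slot stratified logical.
#' @slot seed integer seed controlling fold and split construction.
#' @export
setClass("CVConfig", representation(
  innerK = "integer", innerRepeats = "integer", outerSplits = "integer",
  trainFraction = "numeric", stratified = "logical", seed = "integer"
))
setValidity("CVConfig", function(object) {
  msg <- character()
  if (object@innerK < 2L) msg <- c(msg, "innerK must be >= 2")
  if (object@innerRepeats < 1L) msg <- c(msg, "innerRepeats must be >= 1")
  if (object@outerSplits < 1L) msg <- c(msg, "outerSplits must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0,1)")
  if (length(msg)) msg else TRUE
})

#' @rdname CVConfig-class
#' @param innerK,innerRepeats,outerSplits,trainFraction,stratified,seed see
#'   slots.
#' @return A `CVConfig` object.
#' @export
cvConfig <- function(innerK = 5L, innerRepeats = 1L, outerSplits = 40L,
                     trainFraction = 2 / 3,
                     stratified = TRUE, seed = 1L) {
  new("CVConfig", innerK = as.integer(innerK),
      innerRepeats = as.integer(innerRepeats),
      outerSplits = as.integer(outerSplits),
      trainFraction = as.numeric(trainFraction),
      stratified = as.logical(stratified), seed = as.integer(seed))
}

#' Fitted maximum-likelihood discriminant model
#'
#' Gaussian discriminant with class-specific mean vectors and a pooled
#' within-class covariance matrix over a selected gene subset. The decision
#' rule assigns a sample `x` to the class maximising
#' `x' S^-1 mu_c - mu_c' S^-1 mu_c / 2 + log prior_c`, ties going to the
#' lowest class index. A ridge term is added to the covariance diagonal only
#' when needed for invertibility; the amount actually added is recorded.
#'
#' @slot genes integer indices of the selected genes (into the training
#'   dataset's gene order).
#' @slot geneIds character ids of the selected genes.
#' @slot classes character class levels in increasing order.
#' @slot classMeans numeric matrix, classes x genes.
#' @slot pooledCov numeric matrix, genes x genes, after any ridge addition.
#' @slot priors named numeric class priors summing to 1.
#' @slot ridge numeric >= 0, ridge actually added to the diagonal.
#' @seealso [fitMLHD()], [predictMLHD()]
#' @export
setClass("MLHDModel", representation(
  genes = "integer", geneIds = "character", classes = "character",
  classMeans = "matrix", pooledCov = "matrix", priors = "numeric",
  ridge = "numeric"
))
setValidity("MLHDModel", function(object) {
  msg <- character()
  if (abs(sum(object@priors) - 1) > 1e-12)
    msg <- c(msg, "priors must sum to 1")
  if (!isSymmetric(unname(object@pooledCov), tol = 1e-8))
    msg <- c(msg, "pooled covariance must be symmetric")
  if (object@ridge < 0) msg <- c(msg, "ridge must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Genetic-algorithm configuration
#'
#' Controls the GA search over fixed-size gene subsets ("chromosomes"). The
#' default chromosome size is 5; sizes 10 and 20 are used for model-size
#' comparisons. Fitness is the inner-CV discriminant accuracy. Selection is
#' linear-rank, crossover single-point with duplicate repair, mutation
#' per-locus replacement. `nRuns` independent restarts are pooled into one
#' model population; population size times runs sets how many models are
#' collected (the defaults target a population of about 10,000 models).
#'
#' @slot populationSize integer >= 2.
#' @slot generations integer >= 1.
#' @slot chromosomeSize integer >= 1, genes per model.
#' @slot mutationRate numeric in \[0,1\], per-locus.
#' @slot crossoverRate numeric in \[0,1\].
#' @slot elitism integer >= 0, strictly less than populationSize.
#' @slot goalAccuracy numeric in (0,1\]; a run stops early when reached.
#' @slot nRuns integer >= 1 independent restarts.
#' @slot seed integer master seed; per-run seeds are derived from it.
#' @export
setClass("GAConfig", representation(
  populationSize = "integer", generations = "integer",
  chromosomeSize = "integer", mutationRate = "numeric",
  crossoverRate = "numeric", elitism = "integer", goalAccuracy = "numeric",
  nRuns = "integer", seed = "integer"
))
setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@populationSize < 2L) msg <- c(msg, "populationSize must be >= 2")
  if (object@elitism >= object@populationSize)
    msg <- c(msg, "elitism must be < populationSize")
  if (object@mutationRate < 0 || object@mutationRate > 1)
    msg <- c(msg, "mutationRate must be in [0,1]")
  if (object@crossoverRate < 0 || object@crossoverRate > 1)
    msg <- c(msg, "crossoverRate must be in [0,1]")
  if (object@goalAccuracy <= 0 || object@goalAccuracy > 1)
    msg <- c(msg, "goalAccuracy must be in (0,1]")
  if (object@chromosomeSize < 1L) msg <- c(msg, "chromosomeSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GAConfig-class
#' @param populationSize,generations,chromosomeSize,mutationRate,crossoverRate
#'   see slots.
#' @param elitism,goalAccuracy,nRuns,seed see slots.
#' @return A `GAConfig` object.
#' @export
gaConfig <- function(populationSize = 50L, generations = 40L,
                     chromosomeSize = 5L, mutationRate = 0.01,
                     crossoverRate = 0.8, elitism = 2L, goalAccuracy = 1.0,
                     nRuns = 200L, seed = 1L) {
  new("GAConfig", populationSize = as.integer(populationSize),
      generations = as.integer(generations),
      chromosomeSize = as.integer(chromosomeSize),
      mutationRate = as.numeric(mutationRate),
      crossoverRate = as.numeric(crossoverRate),
      elitism = as.integer(elitism), goalAccuracy = as.numeric(goalAccuracy),
      nRuns = as.integer(nRuns), seed = as.integer(seed))
}

#' Population of evaluated gene-subset models
#'
#' The pooled output of one or more GA runs: one record per chromosome in the
#' final population of each run, with its inner-CV fitness, plus the
#' best-fitness trace per generation. Outer-split accuracies can be attached
#' afterwards with [finalPopulationAccuracy()].
#'
#' @slot records data.frame with columns `run`, `generation`, `fitness`,
#'   `genes` (comma-joined 1-based gene indices) and, once attached,
#'   `outer_mean` / `outer_sd`.
#' @slot bestTrace data.frame with columns `run`, `generation`,
#'   `best_fitness`.
#' @slot nGenes integer, size of the gene universe searched.
#' @export
setClass("ModelPopulation", representation(
  records = "data.frame", bestTrace = "data.frame", nGenes = "integer"
))
setValidity("ModelPopulation", function(object) {
  f <- object@records$fitness
  if (!is.null(f) && length(f) && (min(f) < 0 || max(f) > 1))
    "fitness values must lie in [0,1]" else TRUE
})

#' Bayesian variable-selection configuration
#'
#' MCMC over gene-inclusion indicators of a binary probit model with latent
#' Gaussian augmentation. Regression coefficients carry an independent
#' zero-mean Gaussian prior with variance `priorScale` and are integrated out
#' analytically in the Metropolis-Hastings ratio. The Bernoulli inclusion
#' prior is calibrated so the prior mean model size equals
#' `expectedModelSize` (runs at sizes 10 and 20 reproduce the study setup).
#'
#' @slot expectedModelSize positive integer.
#' @slot priorScale numeric > 0, coefficient prior variance (default 10).
#' @slot nIterations positive integer MCMC sweeps.
#' @slot burnIn non-negative integer < nIterations.
#' @slot nChains integer >= 1 (default 2).
#' @slot moveProbs numeric length 3, probabilities of add/delete/swap moves.
#' @slot nGammaMoves integer >= 1: Metropolis moves on the inclusion vector
#'   per sweep (per latent refresh); more moves speed exploration of the
#'   gene space at negligible cost.
#' @slot seed integer master seed.
#' @export
setClass("BVSConfig", representation(
  expectedModelSize = "integer", priorScale = "numeric",
  nIterations = "integer", burnIn = "integer", nChains = "integer",
  moveProbs = "numeric", nGammaMoves = "integer", seed = "integer"
))
setValidity("BVSConfig", function(object) {
  msg <- character()
  if (object@burnIn >= object@nIterations)
    msg <- c(msg, "burnIn must be < nIterations")
  if (object@priorScale <= 0) msg <- c(msg, "priorScale must be > 0")
  if (object@expectedModelSize < 1L)
    msg <- c(msg, "expectedModelSize must be >= 1")
  if (length(object@moveProbs) != 3L || any(object@moveProbs < 0) ||
      abs(sum(object@moveProbs) - 1) > 1e-9)
    msg <- c(msg, "moveProbs must be 3 non-negative values summing to 1")
  if (object@nGammaMoves < 1L) msg <- c(msg, "nGammaMoves must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname BVSConfig-class
#' @param expectedModelSize,priorScale,nIterations,burnIn,nChains,moveProbs
#'   see slots.
#' @param nGammaMoves,seed see slots.
#' @return A `BVSConfig` object.
#' @export
bvsConfig <- function(expectedModelSize = 10L, priorScale = 10,
                      nIterations = 10000L, burnIn = 2000L, nChains = 2L,
                      moveProbs = c(0.4, 0.4, 0.2), nGammaMoves = 20L,
                      seed = 1L) {
  new("BVSConfig", expectedModelSize = as.integer(expectedModelSize),
      priorScale = as.numeric(priorScale),
      nIterations = as.integer(nIterations), burnIn = as.integer(burnIn),
      nChains = as.integer(nChains), moveProbs = as.numeric(moveProbs),
      nGammaMoves = as.integer(nGammaMoves), seed = as.integer(seed))
}

#' Summary of one BVS chain
#'
#' Post-burn-in record of the subsets visited by the inclusion-indicator
#' sampler: per-subset visit counts, per-gene marginal inclusion frequencies,
#' and a trace of model size and log marginal likelihood.
#'
#' @slot visitedSubsets data.frame with columns `subset` (comma-joined sorted
#'   1-based gene indices; empty string for the null model), `visits`.
#' @slot marginalInclusion numeric vector in \[0,1\], one value per gene,
#'   named by gene id.
#' @slot trace data.frame with columns `iteration`, `size`, `log_marginal`.
#' @slot nIterations,burnIn integers echoing the run configuration.
#' @export
setClass("ChainSummary", representation(
  visitedSubsets = "data.frame", marginalInclusion = "numeric",
  trace = "data.frame", nIterations = "integer", burnIn = "integer"
))
setValidity("ChainSummary", function(object) {
  msg <- character()
  mi <- object@marginalInclusion
  if (length(mi) && (min(mi) < 0 || max(mi) > 1))
    msg <- c(msg, "marginal inclusion frequencies must lie in [0,1]")
  kept <- object@nIterations - object@burnIn
  if (nrow(object@visitedSubsets) &&
      sum(object@visitedSubsets$visits) != kept)
    msg <- c(msg, "visit counts must sum to post-burn-in iterations")
  if (length(msg)) msg else TRUE
})

#' Representative model distilled from a model population
#'
#' A single summary gene subset with its accuracy estimates, the end product
#' of forward selection over a GA model population or of pooling BVS chains.
#'
#' @slot genes character gene ids.
#' @slot method `"GA-MLHD"` or `"BVS"`.
#' @slot endpoint endpoint name.
#' @slot tissue `"normal"` or `"tumour"`.
#' @slot accuracyInner inner-CV accuracy in \[0,1\].
#' @slot accuracyOuter outer-split mean accuracy in \[0,1\] (NA if not
#'   computed).
#' @slot size integer, number of genes.
#' @export
setClass("RepresentativeModel", representation(
  genes = "character", method = "character", endpoint = "character",
  tissue = "character", accuracyInner = "numeric", accuracyOuter = "numeric",
  size = "integer"
))
setValidity("RepresentativeModel", function(object) {
  msg <- character()
  if (object@size != length(object@genes))
    msg <- c(msg, "size must equal the number of genes")
  accs <- c(object@accuracyInner, object@accuracyOuter)
  accs <- accs[!is.na(accs)]
  if (length(accs) && (min(accs) < 0 || max(accs) > 1))
    msg <- c(msg, "accuracies must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Result of the tissue-specificity swap test
#'
#' Per-repeat accuracies of the two-step protocol: Step 1 selects a signature
#' and measures held-out accuracy in its own tissue; Step 2 carries the
#' signature genes into the paired other tissue, retrains there, and measures
#' held-out accuracy. A tissue-specific signature keeps Step 1 accuracy high
#' while Step 2 falls to chance.
#'
#' @slot sameTissue numeric vector of per-repeat Step 1 accuracies.
#' @slot crossTissue numeric vector of per-repeat Step 2 accuracies.
#' @slot endpoint endpoint name.
#' @slot signatureTissue tissue the signature was developed in.
#' @slot signatures list of character gene-id vectors, one per repeat.
#' @export
setClass("SpecificityResult", representation(
  sameTissue = "numeric", crossTissue = "numeric", endpoint = "character",
  signatureTissue = "character", signatures = "list"
))
setValidity("SpecificityResult", function(object) {
  msg <- character()
  a <- c(object@sameTissue, object@crossTissue)
  if (length(a) && (min(a) < 0 || max(a) > 1))
    msg <- c(msg, "accuracies must lie in [0,1]")
  if (length(object@sameTissue) != length(object@crossTissue))
    msg <- c(msg, "sameTissue and crossTissue must have equal length")
  if (length(msg)) msg else TRUE
})

#' Per-component loading profile from a PCA contribution analysis
#'
#' @slot componentIndex positive integer.
#' @slot loadings named numeric vector, one unit-norm eigenvector entry per
#'   signature gene.
#' @slot explainedVariance fraction of total variance in \[0,1\].
#' @slot highlighted character ids of genes with |loading| above the
#'   highlighting threshold (default 0.3).
#' @export
setClass("LoadingProfile", representation(
  componentIndex = "integer", loadings = "numeric",
  explainedVariance = "numeric", highlighted = "character"
))
setValidity("LoadingProfile", function(object) {
  msg <- character()
  if (object@explainedVariance < 0 || object@explainedVariance > 1 + 1e-9)
    msg <- c(msg, "explainedVariance must lie in [0,1]")
  if (!all(object@highlighted %in% names(object@loadings)))
    msg <- c(msg, "highlighted genes must be a subset of the loading names")
  if (length(msg)) msg else TRUE
})

#' Scored enrichment of a gene set against focus genes
#'
#' The (N, G, s, f) hypergeometric enrichment problem: a universe of `N`
#' genes of which `G` are focus genes; a pathway of `s` genes contains `f`
#' focus genes. `pRight` is the right-tail probability of observing at least
#' `f` focus genes by chance, and `score = -log10(pRight)` — the network
#' score whose `> 5` filter corresponds to `p < 1e-5`.
#'
#' @slot N,G,s,f integers, see description.
#' @slot pRight right-tail probability in (0,1\].
#' @slot score numeric >= 0.
#' @export
setClass("ScoredPathway", representation(
  N = "integer", G = "integer", s = "integer", f = "integer",
  pRight = "numeric", score = "numeric"
))
setValidity("ScoredPathway", function(object) {
  msg <- character()
  if (object@f > min(object@G, object@s))
    msg <- c(msg, "f must not exceed min(G, s)")
  if (object@G > object@N || object@s > object@N)
    msg <- c(msg, "G and s must not exceed N")
  if (abs(object@score + log10(object@pRight)) > 1e-9)
    msg <- c(msg, "score must equal -log10(pRight)")
  if (length(msg)) msg else TRUE
})

#' Synthetic paired-data configuration
#'
#' Describes a paired normal/tumour expression study: `nPatients` patients
#' contribute one sample per compartment; `nGenes` filtered-scale genes with
#' Gaussian baseline noise (`noiseSd`); each endpoint has its own disjoint
#' block of `nInformative` genes whose class-mean shift of
#' `effectSize * noiseSd` is planted only in the compartment(s) named by
#' `signalTissue`. Optional equicorrelated gene blocks of size `blockSize` at
#' correlation `blockCorrelation` probe collinearity handling.
#'
#' @slot nPatients,nGenes,nInformative integers.
#' @slot effectSize numeric >= 0, in within-class SD units.
#' @slot signalTissue `"normal"`, `"tumour"` or `"both"`.
#' @slot classBalance numeric in (0,1).
#' @slot noiseSd numeric > 0.
#' @slot blockCorrelation numeric in \[0,1).
#' @slot blockSize positive integer.
#' @slot endpoints character endpoint names (default Gleason-score class and
#'   capsular penetration).
#' @slot seed integer.
#' @export
setClass("SyntheticConfig", representation(
  nPatients = "integer", nGenes = "integer", nInformative = "integer",
  effectSize = "numeric", signalTissue = "character",
  classBalance = "numeric", noiseSd = "numeric",
  blockCorrelation = "numeric", blockSize = "integer",
  endpoints = "character", seed = "integer"
))
setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nInformative > object@nGenes)
    msg <- c(msg, "nInformative must not exceed nGenes")
  if (length(object@endpoints) * object@nInformative > object@nGenes)
    msg <- c(msg, "endpoints need disjoint informative blocks: too few genes")
  if (!object@signalTissue %in% c("normal", "tumour", "both"))
    msg <- c(msg, "signalTissue must be one of normal, tumour, both")
  if (object@classBalance <= 0 || object@classBalance >= 1)
    msg <- c(msg, "classBalance must be in (0,1)")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (object@blockCorrelation < 0 || object@blockCorrelation >= 1)
    msg <- c(msg, "blockCorrelation must be in [0,1)")
  if (object@blockSize > object@nGenes)
    msg <- c(msg, "blockSize must not exceed nGenes")
  if (object@effectSize < 0) msg <- c(msg, "effectSize must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname SyntheticConfig-class
#' @param nPatients,nGenes,nInformative,effectSize,signalTissue,classBalance
#'   see slots.
#' @param noiseSd,blockCorrelation,blockSize,endpoints,seed see slots.
#' @return A `SyntheticConfig` object.
#' @export
syntheticConfig <- function(nPatients = 60L, nGenes = 500L,
                            nInformative = 10L, effectSize = 1.5,
                            signalTissue = "normal", classBalance = 0.5,
                            noiseSd = 1, blockCorrelation = 0,
                            blockSize = 10L,
                            endpoints = c("gleason", "capsular"),
                            seed = 1L) {
  new("SyntheticConfig", nPatients = as.integer(nPatients),
      nGenes = as.integer(nGenes), nInformative = as.integer(nInformative),
      effectSize = as.numeric(effectSize),
      signalTissue = as.character(signalTissue),
      classBalance = as.numeric(classBalance), noiseSd = as.numeric(noiseSd),
      blockCorrelation = as.numeric(blockCorrelation),
      blockSize = as.integer(blockSize),
      endpoints = as.character(endpoints), seed = as.integer(seed))
}
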