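---
title: "Tissue-specific multivariate gene signatures: models and methods"
author: "TissueSig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific multivariate gene signatures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TissueSig)
```

## The scientific problem

In paired tumour/normal expression studies, each patient contributes one
sample from the tumour and one from adjacent, morphologically normal tissue,
together with binary histo-pathological endpoints — here a Gleason-score
class (low vs high differentiation) and capsular penetration (yes/no). Two
questions drive the package:

1. Can small multivariate gene subsets, selected by wrapper methods, predict
   these endpoints from expression in either compartment?
2. Are such signatures *tissue specific* — predictive only in the
   compartment they were developed in — or do they reflect biology shared by
   both compartments?

The second question matters because adjacent normal tissue predicting
tumour features would indicate field effects rather than a read-out of the
tumour itself, and it is answered here by a swap experiment, not by
interpretation.

## Data model

`ExprSet` (extending `SummarizedExperiment`) holds a genes-by-samples
matrix for one compartment, patient identifiers and the binary endpoints.
The synthetic generator `generatePaired()` emulates the paired design:

- one normal and one tumour sample per patient; endpoint labels are drawn
  at the patient level so the pair always agrees;
- per-gene baseline expression is Gaussian, mean 0, standard deviation
  `noiseSd` — the scale of filtered, normalised log-ratio data; optional
  equicorrelated blocks (`blockCorrelation`, `blockSize`) let tests probe
  collinearity;
- each endpoint owns a disjoint block of `nInformative` genes shifted by
  `effectSize * noiseSd` in the positive class, planted only in the
  compartment(s) named by `signalTissue`. With `signalTissue = "normal"`
  the same genes are pure noise in the tumour compartment — the ground
  truth for the specificity test.

Defaults (60 patients, 500 genes, 10 informative genes per endpoint,
effect size 1.5, balanced classes) mirror the scale of the motivating
microarray cohorts after gene filtering: tens of patients, a few hundred
retained genes, and moderately strong per-gene effects. What the generator
does **not** emulate: array platform artefacts, probe-level noise,
normalisation residue, heavy-tailed or gene-specific variances, and
correlation between the two compartments' noise. Passing tests therefore
demonstrate correctness of the machinery and statistical behaviour under a
clean additive Gaussian model, not performance on any real cohort.

## The discriminant classifier and two-level error estimation

The base classifier is a maximum-likelihood discriminant: Gaussian classes
with class-specific means and a pooled within-class covariance over the
selected genes, decision rule
$\hat c(x) = \arg\max_c\, x^\top \Sigma^{-1}\mu_c - \tfrac12
\mu_c^\top\Sigma^{-1}\mu_c + \log \pi_c$, ties to the lowest class index.
Numerical choices:

- **Priors** — empirical training frequencies by default, with an
  `"equal"` switch, since the original discriminant's convention is not
  documented.
- **Singular covariance** — a ridge of $\varepsilon\,\mathrm{tr}(\Sigma)/p$
  is added to the diagonal, $\varepsilon$ starting at $10^{-6}$ and
  escalating tenfold until the Cholesky factorisation succeeds; the amount
  actually added is stored in the fitted model. This only triggers when
  $p$ approaches the fold size.

Errors are estimated at two levels: an inner stratified $k$-fold
cross-validation ($k = 5$) used as the selection fitness, and an outer
average over 40 random stratified splits (2/3 training, 1/3 testing) used
for final reporting. Selection optimises the inner estimate and therefore
biases it upward; the outer estimate, computed only after selection ends,
is the honest one — the package reports both. `CVConfig` adds an
`innerRepeats` knob (default 1): averaging several independent fold
partitions damps fold-assignment noise in the fitness signal. Fold
partitions are fixed for the whole of one GA run, so fitness is a
deterministic function of the gene subset and elitism guarantees a
monotone best fitness.

The inner-CV evaluation of the two-class discriminant is implemented in
compiled code (RcppArmadillo) because it sits in the innermost loop of the
genetic algorithm; all randomness stays on the R side, so results are
bit-reproducible from a single seed.

## Genetic-algorithm selection

Chromosomes are fixed-size gene subsets (default size 5; 10 and 20 are used
for size comparisons). Operators, chosen as standard subset-GA practice
because the original operator set is not printed: linear-rank parent
selection; single-point crossover (rate 0.8) with duplicate repair
(duplicated loci are replaced by uniform random unused genes); per-locus
replacement mutation (rate 0.01); elitism 2. A run stops at `goalAccuracy`
or when generations are exhausted. These defaults are recorded in every
pipeline manifest rather than being presented as anyone's published values.

Many independent restarts matter more than deep single runs: overfit noise
genes are run-specific while genuinely informative genes recur, so the
pooled population (`nRuns × populationSize` models; defaults target about
10,000) concentrates its inclusion-frequency ranking on real signal. This
is also why the representative-model procedure — rank genes by inclusion
frequency in the top 1% (ties at the boundary included) of models, then
forward-select — is preferred to simply taking the best chromosome.

Forward selection keeps a candidate gene only when it improves the inner
estimate by more than a tolerance, and stops after a run of consecutive
failures (patience) or at `maxSize`. The generic default tolerance is
0.001; the specificity-test selector uses 0.02, roughly one standard error
of the repeated inner estimate at these sample sizes, so chance
improvements are not banked. Both are configuration, not constants.

## Bayesian variable selection

The second engine is MCMC over gene-inclusion indicators $\gamma$ of a
binary probit model with latent-variable augmentation: $z_i \sim
N(x_{\gamma,i}^\top\beta, 1)$ with $y_i = \mathbf 1\{z_i > 0\}$. Per sweep:

1. Gibbs refresh of $\beta$ from its Gaussian full conditional;
2. Gibbs refresh of $z$ from sign-truncated normals around the linear
   predictor;
3. a block of Metropolis–Hastings add/delete/swap moves on $\gamma$
   (probabilities 0.4/0.4/0.2; `nGammaMoves` per sweep, default 20 — a
   single move per latent refresh explores a 500-gene space far too
   slowly), each accepted by the ratio of marginal likelihoods
   $p(z\mid\gamma)$ — the coefficients are integrated out analytically
   under their independent $N(0, c)$ prior (default $c = 10$; an intercept
   is always included) — times the Bernoulli prior odds and the Hastings
   correction for the add/delete proposal asymmetry (adding picks one of
   $p-k$ excluded genes, deleting one of $k+1$ included ones; omitting
   this factor silently biases chains toward empty models).

An independence prior is used instead of a $g$-prior because it remains
proper and well-conditioned at $p > n$; $c$ is exposed in `BVSConfig`. The
Bernoulli inclusion rate `expectedModelSize / nGenes` calibrates the prior
mean model size (runs at sizes 10 and 20 reproduce the study setup); in
the vanishing-$c$ limit the chain provably samples this prior, which the
tests use to verify both the calibration and the proposal symmetry. Both
endpoints are two-class, so a binary rather than multinomial probit is
implemented. Truncated normals are drawn by inverse-CDF with the uniform
clamped to $[10^{-12}, 1-10^{-12}]$ to avoid infinite quantiles in extreme
tails.

Chains record post-burn-in subset visits and per-gene marginal inclusion
frequencies. `poolChains()` takes the most-visited subsets across chains,
scores each by cross-validated misclassification under the probit
predictive rule — a deterministic EM-style ridge-regularised estimate of
the coefficients refit inside each training fold, a posterior-mode stand-in
for the posterior-mean linear predictor — and returns the minimum-error
candidate; ties break to the smaller subset, then the higher visit count,
so the result does not depend on chain order. CV folds are drawn once and
shared by all candidates so comparisons are paired.

## Tissue-specificity swap test

`specificityTest()` implements the two-step protocol. Step 1: split the
signature tissue's patients 2/3–1/3 (stratified by endpoint), run the
selector on the training side, fit the discriminant on the training data
restricted to the signature, record held-out accuracy. Step 2: carry the
signature genes into the paired other compartment, split it with the same
patient partition, retrain there from scratch, and record held-out
accuracy. Retraining in Step 2 (rather than reusing Step 1 coefficients)
is deliberate: the question is whether those genes carry any class signal
in the other tissue at all, and retraining gives the cross-tissue model its
best chance. Patients are co-assigned across compartments so no test
patient ever contributes to either training set — the design is paired, and
ignoring this would leak.

With signal planted in the normal compartment only, Step 1 accuracy stays
high while Step 2 falls to the chance level of a balanced binary endpoint
(50%); with the same signal planted in both compartments, Step 2 stays
high. Both behaviours are exercised in the test suite, and the default
synthetic conditions (20 replicate cohorts, 60 patients, 500 genes, 10
informative genes at effect 1.5) are what `scripts/acceptance.R` re-runs.

## PCA gene contributions

`pcaContributions()` decomposes the centred expression of a signature gene
set and reports unit-norm loadings per component, the explained-variance
fraction, and the genes with $|$loading$| > 0.3$ — the working threshold
for a gene contributing materially to a component. The first two components
are reported by default, with an override since component choice for
figures is ultimately visual. Sign convention: each component is flipped,
with its scores, so the largest-magnitude loading is positive; constant
genes are dropped with a warning (error if fewer than two remain).

## Enrichment statistics

The network score for a gene set is the right-tail hypergeometric
probability that a pathway of $s$ genes contains at least $f$ of the $G$
focus genes in a universe of $N$:
$p = \sum_{i=f}^{\min(G,s)} \binom{G}{i}\binom{N-G}{s-i}/\binom{N}{s}$,
reported as $\mathrm{Score} = -\log_{10} p$, with the conventional filter
Score > 5 equivalent to $p < 10^{-5}$. The sum is evaluated in log space
(`lchoose` + log-sum-exp) so large universes are safe, and is unit-locked
in the tests to exact big-integer enumeration. Network membership itself is
user-supplied (GMT files); no interaction-network growth heuristic is
reimplemented, since the knowledge base behind it is proprietary.

Companions: a right-tailed Fisher exact test for canonical-pathway
enrichment (significance at 0.01), classic one-way ANOVA across sample
groups, and a univariate F-ratio ranking (for two classes, $F = t^2$) used
as the baseline selection strategy. ANOVA and univariate outputs carry raw
p-values — the thresholds these analyses replicate are raw — plus a
Benjamini–Hochberg FDR column for reference.

## Pipeline and reproducibility

`runPipeline()` executes simulate → GA and BVS selection → representative
models → specificity → PCA → enrichment from one declarative YAML/list
config. Every stage seed derives from the single manifest seed; the
manifest snapshots the fully-resolved configuration (no silent defaults),
all output paths and their MD5 digests, and the package version. Re-running
an identical configuration reproduces byte-identical TSVs — this is
asserted in the tests. `pipelineReport()` assembles the consolidated
TSV/JSON summary.

## Problem sizes used in the tests

Unit tests run on small instances (tens of patients, tens to hundreds of
genes) chosen so each property is decisively testable; the end-to-end
checks use the default study conditions with the GA at a reduced budget
(population 30, 12 generations, 50–80 runs) and BVS chains of 10–20k
sweeps. These are the package's own desk-scale choices for routine
verification; larger budgets only sharpen the same behaviour.

## Known limitations

- Endpoints are strictly binary; multi-class discriminants and multinomial
  probit are out of scope.
- The GA wrapper's inner estimate is optimistically biased at small $n$ by
  construction; conclusions should rest on the outer estimates, as the
  reporting functions do.
- The generator's Gaussian, compartment-independent noise understates the
  difficulty of real cross-platform data; recovery rates observed here are
  upper bounds.
- `poolChains()` scores candidates with a posterior-mode approximation
  rather than a full posterior predictive; with strongly separated classes
  the EM probit estimate can saturate, which is harmless for ranking.
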