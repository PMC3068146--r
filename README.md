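# TissueSig

Multivariate gene-signature discovery for **paired normal/tumour expression
studies** with binary histo-pathological endpoints (e.g. Gleason-score
class, capsular penetration), and a rigorous test of whether such
signatures are **tissue specific** — predictive only in the compartment
they were developed in — or reflect biology shared by both compartments.
The package is aimed at computational biologists analysing paired-design
cohorts and at methodologists who need a fully seeded, self-contained
test-bed for wrapper gene selection.

## What is inside

Two independent selection engines over a common data model (`ExprSet`,
extending `SummarizedExperiment`):

- **GA-MLHD** — a genetic algorithm over fixed-size gene subsets
  ("chromosomes", default size 5) whose fitness is the stratified
  5-fold cross-validated accuracy of a maximum-likelihood discriminant
  (Gaussian classes, pooled within-class covariance,
  `argmax_c x'Σ⁻¹μ_c − ½μ_c'Σ⁻¹μ_c + log π_c`). A second, outer level —
  40 random 2/3–1/3 stratified splits — provides honest accuracy estimates
  after selection ends. The two-class inner-CV kernel is compiled
  (RcppArmadillo); all randomness stays in R, so everything is reproducible
  from one seed.
- **BVS** — Bayesian variable selection over a binary probit model:
  latent-variable (Albert–Chib) augmentation, coefficients integrated out
  analytically under an independent `N(0, c)` prior, and
  Metropolis–Hastings add/delete/swap moves on the inclusion vector with a
  Bernoulli prior calibrated to a target model size (sizes 10 and 20
  reproduce the study setup).

Around them: representative-model extraction (inclusion-frequency ranking
of the top 1% of models + forward selection), the **tissue-specificity swap
test** (train a signature in one compartment, carry its genes into the
paired compartment, retrain and compare held-out accuracies under a shared
patient partition), PCA gene-contribution profiles (|loading| > 0.3
highlighting), enrichment statistics (the network `Score = −log10` of the
right-tail hypergeometric probability, with the `Score > 5 ⟺ p < 1e-5`
filter; right-tailed Fisher tests; one-way ANOVA; univariate F-ranking),
a seeded synthetic paired-cohort generator, and a YAML-driven pipeline
with a full provenance manifest.

## Worked example

```r
library(TissueSig)

# A paired cohort: 60 patients, 500 genes, 10 informative genes whose
# class signal exists in the normal compartment only.
pair <- generatePaired(syntheticConfig(
  nPatients = 60, nGenes = 500, nInformative = 10,
  effectSize = 1.5, signalTissue = "normal", seed = 7))
pair$normal
#> ExprSet (normal tissue): 500 genes x 60 samples
#>   patients: 60  endpoints: gleason, capsular

# Swap test: select a signature in normal tissue (GA representative-model
# procedure), test it there, then carry the genes into tumour tissue.
res <- specificityTest(pair$normal, pair$tumour, "gleason",
                       signatureTissue = "normal", nRepeats = 3, seed = 7)
res
#> SpecificityResult (gleason, signature from normal tissue, 3 repeats)
#>   same-tissue mean accuracy 0.85; cross-tissue mean accuracy 0.5
```

The signature predicts the Gleason class at ~85% held-out accuracy in the
tissue it was built in, and collapses to coin-flip accuracy (~50%) when its
genes are re-trained and tested in the paired tumour tissue — the defining
signature of a tissue-specific signal. With `signalTissue = "both"` the
cross-tissue accuracy stays high instead.

The same analysis end to end, with both engines and a provenance manifest:

```r
m <- runPipeline(list(seed = 7,
                      simulate = list(nPatients = 60, nGenes = 200,
                                      nInformative = 10, effectSize = 1.5)),
                 outdir = "out")
pipelineReport(file.path("out", "manifest.json"), "out/report.tsv")
```

`out/representative_models.tsv` then holds one row per
(endpoint, tissue, method) with the selected genes, model size, and both
accuracy estimates; `out/specificity.tsv` holds the per-repeat swap
accuracies; re-running the identical config reproduces byte-identical
files.

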