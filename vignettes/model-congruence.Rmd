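---
title: "Methods: congruence scoring and selection of cancer models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: congruence scoring and selection of cancer models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(modelcongr)
```

## The problem and the three-stage design

A cancer model (cell line, PDX, PDO) is useful for studying a tumor subtype
only insofar as its transcriptome behaves like that subtype. Classifier
confidence alone is a poor selection criterion: a model can be assigned to
the target subtype with probability ~1 while sitting many robust standard
deviations from the tumor cohort's center, because a one-dimensional
discriminant only asks *which side* of the boundary a sample falls on.
Conversely, a genome-wide distance can be small while a mechanistically
critical pathway is badly discordant. The package therefore separates three
questions — are the data comparable (harmonization), is the model close to
the target cohort genome-wide (pre-selection), and is it close where it
matters (pathway scoring) — and only models that clear all three are
recommended.

## Harmonization

Three built-in methods, all operating on log2-scale expression with tumors
and models restricted to shared genes:

* **Quantile normalization** maps every sample to the across-sample mean of
  order statistics; ties receive the mean of their target quantiles. It
  equalizes marginal distributions but cannot remove source-specific
  *structure*.
* **Empirical-Bayes batch correction** fits per-gene location/scale batch
  effects, shrinks them across genes (normal prior on locations,
  inverse-gamma on scales, moment-estimated), and removes them. It assumes
  the batches have comparable biological composition; tumor-vs-model batches
  violate this when the model set is dominated by one subtype, which is why
  it is not the default for tumor/model alignment.
* **cPCA + MNN** is a simplified two-step aligner in the style of
  tumor/cell-line alignment tools. Step 1 removes the leading eigenvectors
  of the contrastive covariances `Cov_tumor − α·Cov_model` and symmetrically
  (`n_cpc_remove` from each side, default 4, `α = 1`) — directions of
  variance present in one source only, such as stromal/immune contamination
  in tumors. Step 2 finds mutual nearest neighbor pairs (`mnn_k = 5`)
  between the two sources in the residualized space and shifts each model
  sample by a kernel-smoothed average of the pair difference vectors;
  tumors are the reference and do not move. `mnn_k = 0` disables step 2, so
  `n_cpc_remove = 0, mnn_k = 0` is an exact no-op — useful as a placebo
  configuration and for supplying externally aligned matrices through the
  same interface.

Two numerical choices in the aligner deserve emphasis. First, the smoothing
kernel bandwidth is deliberately wide (3× the median inter-model distance).
The quantity downstream statistics measure is each model's *displacement*
from the tumor cohort; a narrowly local MNN correction moves every model
onto its own matched tumors and absorbs exactly that displacement. A wide
bandwidth makes nearby models share a correction, so the batch vector is
removed while relative geometry is approximately preserved. Second, the
contrastive step removes *tumor-specific variance directions*. When the
candidate models all lie near a single subtype, the between-subtype axis
itself is variance the models do not share, and cPCA will remove it —
destroying the discriminant signal. In that situation run the aligner with
`n_cpc_remove = 0` (MNN only), or align within a pre-restricted sample set;
the pipeline exposes both. This mirrors the practical advice of restricting
alignment to the relevant cluster of samples.

Even a well-behaved MNN correction leaves a common-mode residual: the model
cloud is mapped onto the tumor region it matches, so the *average* candidate
displacement is partially absorbed and all deviance scores shift together by
a fraction of a robust SD. Rankings are much less affected than absolute
scores; see Limitations.

## Sparse discriminant analysis

The discriminant is fitted by penalized optimal scoring on the tumor cohort:
with `Y` the n×2 class indicator matrix and `X` the samples×genes matrix
(each gene centered and scaled to unit variance; constant genes dropped with
a warning),

  minimize ‖Yθ − Xβ‖² + γ βᵀβ + λ‖β‖₁  s.t. (1/n) θᵀYᵀYθ = 1.

The solver alternates (a) an elastic-net regression of `Yθ` on `X` for `β`
(glmnet, with the penalty translated onto glmnet's per-observation scale; a
closed-form ridge solve when λ = 0) and (b) the exact constrained update
`θ ∝ (YᵀY)⁻¹YᵀXβ`, orthogonalized against the trivial constant score and
normalized. Both half-steps are exact minimizers, so the objective trace is
non-increasing — asserted in the tests. `θ` is initialized from a seeded
random vector satisfying the constraint; for a binary contrast the score
subspace is one-dimensional, so the alternation converges in a couple of
iterations and the initialization affects at most the sign, which is fixed
afterwards by orienting the target class to the positive side. Sparsity can
be controlled either by λ directly or by a "largest model with ≤ m nonzero
coefficients" rule on the glmnet path.

On the projected axis a one-dimensional Gaussian LDA with pooled variance
supplies the assignment probability `P_SDA`; priors default to the observed
class proportions (tumor cohorts are typically imbalanced) with an
equal-priors option.

**Penalty scale.** The objective uses the raw residual sum of squares, so γ
and λ scale with the sample size and are *not* dimensionless. The pipeline
defaults (γ = 100, λ = 5) are sized for a cohort of a few hundred samples
over a few hundred genes. This matters more than it may appear: with more
genes than samples and weak penalties, optimal scoring interpolates the
class scores, the within-class spread of the training projections collapses
to nearly zero, and every deviance score explodes (a congruent model can
score DS ≈ 20 where ≈ 0 is correct). Cross-validated *accuracy* cannot
detect this pathology — classification stays perfect — so accuracy-based
tuning (`lam = "cv"`, provided) should be read as a lower bound on the
appropriate penalty, not an oracle. The defaults were chosen so that, on the
generator's reference cohort, a model placed at the target-class mean scores
DS ≈ 0 and planted displacements are recovered ≈ 1:1 (the property is
asserted at fixed seeds in the test suite, not tuned per run).

## Deviance statistics

All deviance statistics use robust location/scale: `μ̂ = median`,
`ŝ = 1.4826 × median(|t − μ̂|)`; 1.4826 is the usual consistency constant
making the MAD estimate the SD under normality.

* `DS_SDA = |c − μ̂_k| / ŝ` on the projected axis; the signed version is kept
  alongside. Smaller = more congruent.
* The two-sided p-value is `2(1 − Φ(|c − μ̂_k| / σ̂))` under a normal null
  centered at the cohort median. The dispersion policy for σ̂ defaults to
  `σ̂ = ŝ` (the only dispersion the robust summary defines); a `"sd"` policy
  (sample SD of the tumor projections) is also exposed because the two
  differ materially on heavy-tailed projections and published per-model
  p-values in this family of methods are not always consistent with the MAD
  scaling. No attempt is made to guess an intent: the policy is explicit.
* The 95% bootstrap CI resamples the tumor projections (B = 1000), recomputes
  μ̂, ŝ, DS per replicate, and takes the percentile interval (R quantile
  type 7) of `log2(DS)`, back-transformed. Replicates with zero MAD or zero
  DS are dropped from the log transform with a logged count rather than
  epsilon-floored; both events have probability ~0 for continuous
  projections.
* `DS_gene = (c_g − μ̂_g,k) / σ̂_g` with σ̂ the scaled MAD of the target-class
  tumors for that gene; positive = model over-expresses. Genes with zero MAD
  are excluded (NA) with a warning.
* `DS_path` is the geometric mean of |DS_gene| over a pathway's DE genes —
  chosen over the arithmetic mean to damp single-gene outliers. An exact
  zero yields 0 (the limit), NA genes are excluded, and an empty set errors.
* The `DS_path` p-value is one-sided and empirical: each target-class tumor
  sample is scored as if it were a model, **with itself excluded** from the
  median/MAD computation (leave-one-out; scoring a sample against statistics
  containing it biases the null toward zero). The add-one estimator
  `p = (1 + #{null ≥ obs}) / (1 + N)` avoids p = 0. Small p = worse
  congruence. The null uses target-class tumors only, matching the
  definition of the score itself.

## Differential expression and enrichment

The default DE backend is a per-gene Welch t-test on log2 expression
(`welch_log`), with the effect equal to the class-mean difference (the log2
fold change). A simplified negative-binomial Wald backend (`nb_wald`;
per-gene `MASS::glm.nb` with a class factor and log-library-size offset) is
provided for count matrices. Neither reproduces a full count-model pipeline
(no dispersion shrinkage, outlier refitting or independent filtering), and
externally computed DE tables — e.g. from DESeq2 — can be injected anywhere
a DE result is consumed (`de = list(external = <table>)`). A gene is DE when
|FC| > 1.5 *and* BH-adjusted p < 0.05 (both configurable; the conjunction is
strict).

Preranked GSEA uses the weighted Kolmogorov–Smirnov running statistic on all
genes ranked by log2FC (weights `|rank|^p`, default p = 1; p = 0 is the
classical KS statistic). The null is built from random gene sets of matching
size; crucially, the null sets are drawn as gene subsets *in input-gene
order*, not as positions in the sorted list, so the draws are independent of
the rank values and negating every rank negates every null ES exactly —
making NES antisymmetry under rank negation exact rather than approximate.
Exact |max| = |min| ties in the running walk (common rationals from the
miss-step side) are broken by the walk's total area, which also negates
exactly under reversal. `NES = ES / mean(|null ES| of matching sign)`;
p-values are two-sided empirical with the add-one rule, BH-adjusted across
pathways. Pathway "size" is the pathway∩ranked-universe count (the common
preranked convention).

Pathway filters use strict inequalities exactly as printed in the underlying
selection rules: analysis set `n_DE > 20`; selection set additionally
`30 < size < 200` and `|NES| > 1.5`. Pinned pathways are carried into the
selection set with a flag and are excluded from the ranking average; pinned
models likewise bypass pre-selection without affecting any other model's
scores (asserted as an invariant).

## Pipeline semantics

Pre-selection keeps models with `P_SDA > 0.5` and `pval(DS_SDA) > 0.05`
(base) and by default requires the stringent version (`> 0.8`, `> 0.1`) for
entry into pathway scoring, mirroring the two-tier screening this method
family uses; `stage = "base"` relaxes that. The final ranking is the
ascending arithmetic mean of `DS_path` over the non-pinned selection
pathways, ties broken by `DS_SDA`, then model id. Every stage's table is
written as TSV plus a `report.json` with the configuration and seed embedded;
all randomness derives from the single config seed, and identical config +
seed produces a byte-identical report (asserted).

## What the synthetic generator emulates — and what it does not

The reference scenario is stated once and used everywhere: 100 + 100 tumors
of two subtypes over 300 genes; 72 signature genes with a ±2 log2-unit
subtype effect (half up, half down — real subtype signatures run in both
directions); a genome-wide background subtype difference of SD 0.3 log2
units on every gene (real contrasts are not exactly null off-signature, and
an all-or-nothing rank distribution makes preranked enrichment statistics
pathological); per-sample Gaussian noise of SD 0.5 log2 units. Candidate
models are *noiseless* displaced profiles: the target-class mean moved
`d × noise_sd` along the unit signature axis, so the true deviance is known
(≈ d) by construction. Pathway discordance adds alternating-sign offsets on
one pathway's genes, leaving the genome-wide projection untouched — the
model that sails through stage 2 and fails stage 3. Optional anchor models
(noisy target-class draws sharing the batch offset) emulate the catalogue of
existing models that, in practice, anchors tumor/model alignment. A
lognormal–Poisson map supplies a counts variant for the NB backend.

Deliberately not emulated: gene–gene correlation, count-level mean–variance
structure outside the counts variant, multiple model batches, passage
drift, intra-model heterogeneity, and microenvironment admixture. A green
test therefore establishes that the statistics and their couplings behave as
specified in a world where their assumptions hold — not that any particular
biological dataset satisfies those assumptions.

## Known limitations

* **Binary contrasts only.** One discriminant direction; multi-class
  selection is out of scope.
* **Alignment absorbs common displacement.** Any tumor/model alignment that
  matches models to tumors removes part of the average candidate
  displacement; absolute deviance scores after `cpca_mnn` are biased low by
  a shared offset (fractions of a robust SD in our experiments), while
  rankings are more stable. In a planted batch-offset scenario with 80
  anchors, the unaligned pipeline essentially never ranks the truly
  congruent model first, and the aligned pipeline recovers it in roughly
  three quarters of runs rather than the ~90% an idealized account would
  suggest — the d = 1 distractor sits at the desk-scale resolution limit of
  pathway scoring once the correction's residual bias lets it into the final
  round. The corresponding test asserts the contrast at honest bounds.
* **Pathway-score resolution.** With ~100 tumors and ~36-gene pathways, the
  per-gene median noise (~0.13 robust SDs) is comparable to the gene-level
  footprint of a d = 1 genome-wide displacement; `DS_path` separates
  pathway-level discordance sharply but fine-grained genome-wide distances
  only weakly. That division of labor between `DS_SDA` and `DS_path` is by
  design.
* **p-value calibration is asymptotic in the cohort size.** The normal-tail
  p-value treats μ̂, σ̂ as known; at n = 200 the null rejection rate at
  α = 0.05 is ≈ 0.055–0.06 (within the accepted band, asserted), and it
  degrades for small cohorts.
* **The NB backend is a convenience**, not a substitute for a dedicated
  count-model DE tool; inject an external DE table for production use.
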