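---
title: "Methods: imputing and refining missense variant-effect maps"
author: "maveImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imputing and refining missense variant-effect maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maveImpute)
```

# The problem

A multiplexed assay of variant effect (MAVE) couples a functional
selection to deep sequencing and scores thousands of variants of one
protein at once. Coverage is never uniform: variants poorly represented
in the mutagenized library are measured noisily or not at all, so the
raw variant-effect (VE) map has holes and soft spots. `maveImpute`
completes the map by training a per-protein regression model on the
well-measured variants, predicting the missing ones, and combining
model and measurement where both exist.

The pipeline assumes (i) the assay includes stop and synonymous
variants, or the scores arrive pre-normalized; (ii) function scores of
variants at the same position are correlated (the basis of the
positional-mean feature); and (iii) measurement noise is approximately
Gaussian on the normalized score scale, which makes inverse-variance
weighting the right combination rule.

# Normalization and the adaptive correction

Scores are rescaled so the stop-variant median is 0 and the synonymous
median is 1. The transform is affine, so it also rescales each
variant's standard deviation by 1/|Syn~med~ − Stop~med~|; whether the
original service rescales dispersions is not something the package can
observe, but leaving sds on the raw scale would make them incoherent
with the rescaled scores, so rescaling them is the only self-consistent
choice. Medians use the usual midpoint convention for even counts.
When either anchor class is absent the pipeline refuses to guess and
asks for pre-normalized input (`prenormalized = TRUE`), which skips
anchoring but still applies the adaptive correction unless `flip =
FALSE` — the two steps are independent.

Scores above 1 ("apparently adaptive") are transformed to their
reciprocal 1/X. The transform is continuous at 1, maps (1, ∞) into
(0, 1), and is idempotent after one pass; it is applied once,
before modeling, and never re-applied to refined outputs. Standard
deviations ride along by the first-order delta method (sd′ = sd/X²),
keeping uncertainty coherent on the flipped scale.

# Features

Each missense variant gets a fixed 21-column feature vector: the
positional mean of measured missense scores, four physicochemical
properties (Kyte–Doolittle hydropathy, Zamyatnin volume, formal charge
at pH 7, binary polarity) for the wild-type residue, the substituted
residue, and their difference, the BLOSUM62 entry, three optional
external predictor scores (PolyPhen-2, PROVEAN, SIFT, consumed as
columns, never computed), and optional structure features (one-hot
secondary-structure class, relative solvent accessibility). The
property scales are the standard representatives of the categories
"chemical and physical properties of the amino acids"; the exact
membership of the original service's feature set is not public, so the
schema implements every named category with canonical choices.

Two deliberate decisions:

* **Self-exclusion.** For a measured training target the positional
  mean is computed without the target's own score; otherwise the model
  could copy its label through the feature. At prediction time (the
  target is unmeasured) all measured missense variants at the position
  contribute. A test perturbs a target's score and asserts its own
  feature does not move.
* **Anchors are not modeled.** Stop and synonymous variants are
  excluded from the model's targets: their values are fixed by
  normalization, and predicting them would only let anchor noise leak
  into the missense model.

# Model, cutoff and importance

The regressor is a gradient-boosted-tree ensemble (xgboost backend)
with 500 trees, learning rate 0.05, maximum depth 3, subsampling 0.8 —
conservative defaults for a few hundred to a few thousand rows of
tabular data, exposed via `pipelineConfig(model = ...)`. Trees route
missing values natively, so absent predictors or structure never abort
a run. Training is deterministic given the pipeline seed (single
thread, seeded subsampling).

The quality cutoff keeps poorly measured variants out of training.
When the user does not fix it, the top 20% of missense variants by
quality score are held out as a test set (ties at the boundary break
deterministically by position and substitution), candidate cutoffs are
the deciles of the remaining pool's quality distribution (≤ 10
trainings), and the cutoff minimizing test RMSE wins; exact ties go to
the smaller cutoff because more data is preferable when performance is
indistinguishable. Candidates leaving fewer than 10 training records
are skipped. The held-out test set never enters any candidate's
training set.

Feature importance is the number of times a feature is used for
splitting, each split weighted by its squared-error improvement,
averaged over trees and normalized to sum 1. It is computed directly
from the dumped tree structure rather than any pre-aggregated summary,
so the definition is explicit and testable: a model trained on a
single informative feature reports importance 1 for it, and features
never split on report 0.

`compareMethods()` evaluates the ensemble against a random forest, a
linear model and a positional-mean baseline on one shared 10-fold
partition (identical folds for every method; validated as an exact
partition in the tests). Methods without native missing-value routing
get training-fold median fill plus per-feature missingness indicators.
An RBF support-vector comparator is available behind `includeSVM =
TRUE` but is off by default: it is scale-sensitive and slow at this n,
and the comparison exists to contextualize, not to assert a winner.
The reported CV RMSE of the final model is computed on post-cutoff
training records — the model never sees below-cutoff records, so its
honest generalization estimate should not include them either.

# Error model

With `n_reps ≥ K` replicates the replicate-based standard error is
trusted. Below that, the measured and prior variances are pooled with
`priorDf` pseudo-degrees of freedom:

σ²~reg~ = (d₀·σ²~prior~ + (n−1)·σ²~meas~) / (d₀ + n − 1)

This interpolates in variance space: at n = 1 it returns the prior
exactly (there is no within-variant dispersion to use), the measured
term dominates as replicates accumulate, and at n ≥ K the formula is
bypassed in favor of the measured value. The gap |σ~reg~ − σ~meas~|
is non-increasing in n, which is the numerically honest version of
"converges to the measured value". Defaults K = 4 and d₀ = 2 reflect
common MAVE replication depths (3–8 replicates) and a prior worth two
observations; both are config keys.

The prior itself regresses dispersion on function score. The fit is a
weighted penalized spline (mgcv) in **variance** space, in two passes:
a first fit with degrees-of-freedom weights, then a refit with weights
df/σ̂⁴ matching the sampling variance of s². Variance space matters
because E[s²] = σ² makes the fit unbiased for replicate-estimated
sds, whereas fitting log s (or log s²) and exponentiating back is
biased low by a df-dependent factor (≈ 17% at 4 replicates) — enough
to matter for the weights used downstream. Evaluation is clamped to
the observed score range; sparse data (fewer than 5 distinct scores)
degrade to a weighted line, then to a constant, and fewer than 10
usable records fall back to the constant median sd with a warning.

Imputed scores need an uncertainty too, and the model provides no
per-variant intervals by design. Each imputed cell carries the global
10-fold CV RMSE, floored at 1e-6 so inverse-variance weights stay
finite on noise-free synthetic data, and optionally inflated (config
`error$lowCoverageInflation`) at positions with fewer than 3 measured
missense variants, where the positional-mean feature is weakest. This
is the simplest estimate consistent with how the model is validated;
per-variant predictive intervals are a non-goal.

# Refinement and assembly

A measured score m (σ~m~) and its prediction i (σ~i~) combine as the
inverse-variance-weighted mean, with combined error
(1/σ²~m~ + 1/σ²~i~)^−1/2^. The refined score always lies between its
inputs and its error never exceeds the smaller input error.

Measurements **below** the quality cutoff were judged not reliable
enough to train on; the map conservatively replaces them by pure
imputation rather than letting them pull the refined value. The
alternative (`belowCutoff = "refine"`) is one flag away for users who
prefer to keep every measurement in play. Synonymous cells are fixed
at 1 (that is their defined value on the anchor scale) with the
measured record's regularized σ where one exists, and blank otherwise;
stop cells carry their measured rescaled score or stay blank. Neither
is ever imputed.

# The synthetic generator

`generateSynthData()` emulates the study conditions the tests run
under: an additive truth (uniform position effects on [0, 1.05] plus
Gaussian substitution effects, sd 0.15, clamped to [0, 1.25] so a few
percent of variants land above 1 and exercise the flip), raw scores on
a deliberately shifted axis (stop ≈ 0.15, synonymous ≈ 1.6) so
normalization is always non-trivial, replicate counts uniform on 1–8,
replicate noise sd 0.1 on the normalized scale times a per-variant
lognormal factor (sdlog 0.5), quality = n_reps/(1 + noise sd) so the
cutoff search has signal, 80% anchor coverage and 30% missense
censoring by default. The truth table covers all 21·L cells, making
masked-cell RMSE and correlation computable with no external data.

What it does **not** emulate: read-count sampling and selection
dynamics, position-position epistasis beyond the optional noise,
systematic batch effects, and any relationship between the truth and
real biophysics (substitution effects are random, not
hydrophobicity-driven). Passing tests therefore demonstrate that the
pipeline recovers the structure it models — positional plus
substitution effects under heteroskedastic noise — not that imputation
accuracy on any real protein will match the synthetic numbers.

Test problem sizes: unit tests use maps of 20–50 positions with a
reduced 60-tree configuration; the end-to-end recovery checks use
L = 100 (masked-cell RMSE below the positional-mean baseline, truth
correlation r > 0.8 at noise sd 0.1) and L = 60 (purely positional
truth puts `pos_mean_score` on top of the importances) with the
default 500-tree model — sizes chosen as the smallest at which the
generator's effects are well identified.

# Numerical conventions and degenerate inputs

* Anchor rescaling requires Syn~med~ ≠ Stop~med~; equality is a
  validity error, not a NaN.
* Duplicate variant rows merge by replicate-weighted mean with pooled
  sd over the combined replicate set; merging, not rejection, because
  MAVE exports often shard by tile.
* Median-of-two anchor identities hold to ~1e-16 (floating residue of
  the midpoint); tests assert them at 1e-12.
* Quality ties at the 20% boundary and equal-RMSE cutoff ties resolve
  deterministically (key order; smaller cutoff).
* All randomness — fold assignment, subsampling, synthetic data —
  derives from explicit seeds; two runs of `runPipeline()` with the
  same config and seed write byte-identical map files.
* The SVG renderer is a pure formatter: no device state, no
  randomness, byte-identical output for identical input; scores are
  clipped to [0, 1.2] and the color position saturates at 1.

# Limitations

* The model is per-protein and is never transferred between proteins;
  a new map means a new training run.
* Imputed-cell uncertainty is global (CV RMSE), not per-variant.
* The error-model pooling formula is a concrete, limit-correct reading
  of "update the measured σ with a prior estimate"; other shrinkage
  weightings are defensible and would change refined errors slightly.
* External predictor and structure columns are consumed, never
  fetched; the package is offline by construction.
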