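---
title: "Modeling drug response from multi-omic cell-line panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling drug response from multi-omic cell-line panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsig)
```

`pharmsig` models therapeutic response in a molecularly profiled cancer
cell-line panel and transfers the resulting signatures to tumor profiles.
This vignette is the package's account of the methods: the models, their
assumptions, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## Dose-response measures

A raw plate record holds, for one cell line and compound, two background
ODs, an untreated triplicate, treated triplicates at nine strictly
increasing concentrations, and a separate time-zero (T0) plate summary.
Background correction subtracts the mean of the same-plate background wells
from every OD; triplicates are summarized by their **median**, which
tolerates a single failed well without influence from its magnitude. A
record whose corrected untreated control is non-positive is rejected — it
carries no growth information.

Percent growth follows the NCI two-branch convention relative to time zero
(`t0`) and untreated control (`C`):

$$g(T) = \begin{cases}100\,(T - t_0)/(C - t_0) & T \ge t_0\\
100\,(T - t_0)/t_0 & T < t_0\end{cases}$$

which is continuous at `T = t0`, equals 100 for untreated growth, 0 at
stasis and −100 at complete kill. GI50 is the concentration where growth
first crosses 50, TGI where it crosses 0. Crossings are located by linear
interpolation in log10(concentration) within the first (lowest
concentration) bracketing interval; a curve already at or below the level
at the lowest tested concentration clamps to that edge (`at_min`), one that
never reaches the level clamps to the highest (`at_max`). Clamping flags
preserve the censoring information; both endpoints are reported as
−log10(molar), so larger values mean more sensitive. Replicate plates for
the same (line, compound) pair are combined by the median GI50.

Compounds with low variation across the panel carry no contrast to learn
from and are eliminated. The filter keeps compounds with GI50 standard
deviation ≥ `sd_floor` (default 0.5 log10 units — half an order of
magnitude of spread) and a clamped-measure fraction ≤
`offscale_max_fraction` (default 0.5). Both are configurable; the original
elimination rule behind the published panel is not stated anywhere, so
these defaults are this package's own calibration and reduce a synthetic
138-compound panel with realistic spread to roughly the retained fraction
seen in practice (about two-thirds).

## Response labels

For each compound the dichotomization threshold is the arithmetic mean GI50
over the **core** cell lines — the lines with response data and several
molecular data sets; any line with a GI50 is then labeled against that
threshold, strictly above = sensitive. A line exactly at the threshold is
labeled resistant: when in doubt, do not recommend treatment. Single-class
labelings are flagged unusable rather than silently fitted.

## Weighted LS-SVM

The least-squares SVM replaces the hinge loss with a squared error, so
training reduces to one dense linear solve of the (N+1)×(N+1) saddle
system shown in the README. Class imbalance is corrected by per-sample
weights `w_i = N / (2 N_class(i))`, giving each class equal total weight
(balanced classes give all weights 1). The system is solved directly; a
singular system gets one ridge-jittered retry (1e−8 on the diagonal)
before erroring. Continuous features are standardized to zero mean and
unit variance **on the training lines only**; binary mutation indicators
pass through as 0/1.

Because downstream components consume probabilities, decision values are
calibrated with a Platt sigmoid fitted on the training decision values
using Platt's smoothed targets `(N₊+1)/(N₊+2)` and `1/(N₋+2)`. The
smoothing matters: panels are small and often linearly separable, where an
unregularized logistic fit diverges and saturates every probability to
exactly 0 or 1, destroying the ranking information the toolbox depends on.

Grid-search feature optimization ranks features inside each inner
cross-validation training fold by absolute two-sample t statistic
(configurable to absolute correlation; features that separate the classes
perfectly, with zero within-class variance, rank above any finite t) and
scores every (feature count k, γ, kernel) cell by mean inner-fold AUC.
Defaults: k ∈ {5, 10, 25, 50, 100, 250, 500}, γ ∈ 10^{−2..2}, linear
kernel, 3 inner folds. Ties prefer the smallest k, then the smallest γ —
a parsimony rule. One consequence is worth knowing: when the signal is
strong enough that the inner AUC saturates at 1.0 from k = 5 upward, the
optimizer returns a minimal 5-feature signature even if more true markers
exist; the signature object therefore also carries the top-100 feature
**ranking**, which is the right object for marker-recovery questions and
mirrors how ranked feature lists are reported in this field.

Random forests are probability forests (default 1000 trees, `mtry = √p`,
impurity importances), deterministic given a seed.

## Evaluation protocol

Accuracy is the mean rank-statistic AUC over `n_splits` random stratified
divisions into 2/3 training and 1/3 test lines (default 100 splits;
stratification avoids single-class folds at panel sizes near 48). The
entire pipeline — standardization, the supervised best-feature-per-gene
reduction for multi-level platforms, feature ranking, grid search,
calibration — is refit on each training set only. The per-gene reduction
is supervised, so applying it before splitting would leak test labels into
feature choice and inflate AUC; the package only ever applies it inside
training folds. A test suite canary checks that a feature predictive only
on test lines is not selected above chance.

Two properties of this protocol deserve honesty. First, on a finite panel
of n = 48 lines and 1000 features, the per-compound mean AUC under a null
compound (labels independent of features) is not a point at 0.5: chance
feature-label correlations of magnitude up to √(2 ln p / n) ≈ 0.5 survive
feature selection, and within-panel cross-validation with selection has a
small negative bias, so the null mean-AUC distribution has a standard
deviation near 0.06 and mean near 0.49. About 85–90% of null compounds
land in [0.4, 0.6]; the band is a ~1.5σ interval, not a guarantee.
Second, the multi-split mean is an in-panel estimate; transfer to
independent cohorts is measured separately by the toolbox.

## Data-type comparison

Per compound and data type the best AUC (over methods, and over gene-level
versus all-feature sets for multi-level platforms) forms a compounds ×
data-types grid. Data types are compared on the compounds complete in all
types: an overall one-way within-subject ANOVA with compounds as subjects,
all pairwise paired t-tests with Benjamini–Hochberg adjustment (the
correction method is this package's choice; FDR control is the norm in
this setting), and a ranking by mean AUC with tie-aware win counts.
Identical columns give a paired p of 1; a constant nonzero shift is the
degenerate limit of the paired t and is reported as p = 0.

The subtype baseline fits the same LS-SVM protocol on one-hot
transcriptional-subtype indicators plus the ERBB2-amplification flag. A
compound is *subtype-sufficient* when the baseline already exceeds AUC 0.7
and the best omics model adds < 0.1; *omics-adds* when the best omics
model exceeds 0.7 and adds ≥ 0.1; otherwise *weak*. Boundaries are exact:
AUC exactly 0.7 does not pass the strict floor, a delta of exactly 0.1
counts as omics-adds (with a 1e−9 tolerance so decimal deltas survive
binary floating point).

## Patient toolbox

Applying a signature to tumors requires, per data type, at least 80% of
the signature's features in the tumor data (below that the call refuses
with the observed fraction — predictions from a half-missing signature are
not meaningful); absent features are imputed with their training-panel
means, and standardization always uses the training-panel parameters.

Per-compound cutoffs come from the cohort's probability distribution:
univariate normal mixtures with 1–3 components are fitted by EM (via
mclust) and the count chosen by BIC. Cutoffs sit at the
density-intersection points of adjacent components — the probability where
cohort membership flips — found by root-finding between the component
means. With two components the single intersection is the
intermediate|sensitive boundary and the resistant|intermediate boundary
falls at a configurable quantile (default 0.25) of the lower component;
with one component the rule falls back to the 0.25/0.75 data quantiles,
flagged `unimodal`. Status assignment resolves boundaries toward the less
responsive status, and the display rescaling maps [0, c1], (c1, c2] and
(c2, 1] linearly onto thirds of [0, 1], so the three statuses occupy equal
display bands and the cutoffs land exactly on 1/3 and 2/3.

The report keeps compounds with model AUC > 0.7 for which at least one
patient exceeds probability 0.65 (both floors strict), and orders each
patient's compounds by probability, ties broken by larger in-vitro GI50
dynamic range — among equally probable options, prefer the compound with
more room between its most sensitive and most resistant line — then by
compound id for determinism.

Signature coherence asks whether the co-regulation structure of a
signature's genes transfers from cell lines to tumors: edges are unordered
gene pairs with |Pearson r| above `r_threshold` (default 0.5, a moderate
correlation; the original threshold is unstated) computed separately in
each cohort, the statistic is the Jaccard coefficient of the two edge
sets, and significance comes from random equal-size gene sets drawn from
the shared genes (default 9999 draws). A null set with no edges in either
cohort counts as J = 0 — it exhibits zero reproducible co-regulation —
rather than being dropped, which would shrink the permutation denominator
and inflate p.

## Synthetic data: what it emulates, and what it does not

The generator draws subtypes from configurable proportions (default
0.44/0.34/0.13/0.09 luminal/basal/claudin-low/normal-like, the mix of a
real breast panel), gives a fraction of features subtype-dependent mean
shifts, plants per-compound effects, and draws the seven-gene mutation
panel from subtype-dependent Bernoulli rates (TP53 enriched in
basal/claudin-low, PIK3CA and CDH1 in luminal). For a feature-driven
compound a latent per-line burden drives both the planted features
(`effect × burden + noise`) and the true GI50
(`base + spread × burden + noise`); subtype-driven compounds shift GI50
for a target subtype instead. Defaults: 48 lines, 1000 features per type,
GI50 base 7 (100 nM), spread 1 log10 unit, residual noise 0.1.

Plates are generated by inverting the dose-response model: a percent-growth
line in log10(concentration) crossing 50 exactly at the true GI50, with
time-zero 100 and control 200 so signal = 100 + growth in both branches,
written as OD triplicates over a 9-point grid spanning 1 nM–10 µM. The
slope default of 70 percent-growth per decade describes a steep responder
(Hill slope ≈ 1.5) and fixes how assay noise propagates: with 5% OD noise
and median-of-3 triplicates the interpolated GI50 carries an error SD of
about 0.08 log10 units. At zero noise the round trip is exact to floating
point, and clamping flags fire exactly when the truth lies outside the
tested range. Tumor cohorts reuse the panel's feature grammar, with a
known responder fraction carrying the planted shifts.

Everything is Gaussian with linear effects — deliberately, for
analyzability. Real data have heavy tails, batch structure, correlated
features, platform-specific detection limits and missingness patterns none
of which the generator reproduces. Passing the recovery tests therefore
shows the machinery is correct and unbiased under its stated model, not
that real panels will yield AUC 0.99; published panels of this kind reach
AUC > 0.7 for roughly half of compounds.

## Numerical and protocol choices

- Problem sizes in tests and the acceptance script: recovery at 48 lines ×
  1000 features with 20 evaluation splits; the null calibration over 50
  compounds at 100 splits (the evaluation default); 20 seeded replicates
  for the subtype-sufficiency and cutoff-recovery checks. These sizes give
  stable Monte-Carlo estimates at a few minutes on one CPU.
- Missing values: features missing in > 20% of modeling lines are dropped,
  the rest mean-imputed (configurable). The paper-scale datasets this
  mirrors are largely complete; heavier missingness deserves real
  imputation upstream.
- Serialization: signatures round-trip through versioned JSON at full
  numeric precision; the predictive model is reconstructed
  deterministically from the stored training payload (LS-SVM re-solve; RF
  re-grown from its seed), so a written-and-read signature predicts
  identically to the original.
- Determinism: every stochastic operation takes a seed; multi-split
  evaluation derives one sub-seed per split, so results are reproducible
  and independent of execution order.
- Degenerate inputs are flagged, not silently fixed: single-class labels
  (`usable = FALSE`), zero-variance features in association tests
  (`zero_variance`), cohorts with no events (`no_events`), unimodal
  probability distributions (`unimodal`), empty coherence unions.

## Known limitations

No 4PL/Hill curve fitting (interpolation only, as the endpoints are
defined); no plate-effect normalization beyond background subtraction; no
batch correction or platform normalization; binary response only; the
subtype baseline requires annotations for all labeled lines; in-panel AUC
estimates carry the selection-bias caveats described above.
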