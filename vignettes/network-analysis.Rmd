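---
title: "Methods: partial-correlation networks, relative importance, and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation networks, relative importance, and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilnet)
```

This vignette is the package's account of its statistical machinery: what is
estimated, under which assumptions, which knobs matter, and where genuinely
open design choices were settled.

## The model

The analysis treats p scale scores per participant (overall quality of life,
behavioral coping, positive appraisal style, self-management ability,
physical activity, policy stringency — or facet-level variants) as jointly
Gaussian. A Gaussian graphical model (GGM) is then a sparsity pattern on the
precision matrix K = Σ⁻¹: a missing edge i–j means variables i and j are
conditionally independent given all others, and a present edge carries the
partial correlation

ρᵢⱼ = −Kᵢⱼ / √(Kᵢᵢ Kⱼⱼ).

`partials_from_correlation()` implements exactly this standardized negative
inverse. The Gaussian assumption is an approximation for bounded sum scores;
it is the standard working assumption in psychometric network analysis, and
it enters twice — in the likelihood used for model selection and in the
multivariate-normal synthetic-data generator.

### Constrained maximum likelihood

The inner step of structure search is the maximum-likelihood fit of a GGM
with a *fixed* edge structure: maximize log det K − tr(SK) subject to
Kᵢⱼ = 0 off the structure. `fit_constrained_ggm()` solves this by cyclic
regression updates of the implied covariance W (compiled code, since the
search and the stability bootstraps call it hundreds of thousands of times).
The ML first-order conditions are moment constraints — W must equal the
sample matrix S on the diagonal and on every allowed edge — and the tests
verify both directly and against a generic numerical optimizer over the free
precision entries.

Numerical choices: convergence is declared when the largest absolute change
of W in one sweep falls below 1e-8 (on the correlation scale all entries are
O(1), so this is effectively machine-level agreement of the moment
conditions); the sweep cap is 10,000, and non-convergence is an error rather
than a warning, since a half-converged fit would silently corrupt the EBIC
ranking of structures.

### Stepwise EBIC structure search

`ggm_model_select()` scores a structure with k edges by

EBIC = −2·loglik + k·log n + 4·k·γ·log p,

with γ = 0 by default, i.e. plain BIC — the convention for unregularized GGM
search on samples of this size. k counts only the free off-diagonal
parameters: the p diagonal entries are free in every model and would add a
constant.

The search has two stages:

1. **Initialization path.** The saturated partial-correlation matrix is
   thresholded at 100 log-spaced levels from its largest absolute entry down
   to 1% of it (`n_levels`, `min_ratio`; both configurable). Distinct masks
   along the path — plus the empty and saturated structures — are refit by
   constrained ML, and the EBIC-minimal candidate seeds the search. The path
   scan makes the greedy stage start near the right sparsity level instead
   of walking edge by edge from empty.
2. **Greedy stepwise.** Every single-edge addition or removal of the current
   structure is refit and scored; the best strict EBIC improvement is
   accepted; repeat until no toggle improves. Ties (within 1e-10) are broken
   toward the sparser model, then by lexicographic edge order, and a visited
   set rules out cycling — the procedure is fully deterministic and returns
   a local optimum at which no single toggle lowers EBIC. On three-node
   problems the tests check it against exhaustive enumeration of all eight
   structures; for six nodes at cohort sizes it recovers the generating
   structure essentially always.

Correlations are Pearson correlations of the scale scores, treated as
continuous. No polychoric/threshold option is offered in this version: the
node variables are sums or means over many Likert items (or continuous
composites), where Pearson treatment is customary.

## Relative importance (LMG)

Conditional dependence is undirected. To say something about *predictive
direction*, the selected GGM structure is imposed on a relative-importance
analysis: each node j with neighbors N(j) is regressed on exactly N(j), and
the model R² is decomposed by the LMG metric — predictor i's contribution is
its incremental R² averaged over all |N(j)|! orderings in which the
predictors can enter. This is the Shapley value of the R² game: the only
decomposition that is symmetric, exact (contributions sum to R²) and
nonnegative. `lmg_contributions()` computes it from covariance algebra over
the 2^k predictor subsets with factorial weights, which is algebraically
identical to ordering enumeration but k!/2^k times cheaper; the test suite
verifies exact agreement with a literal ordering-enumeration oracle up to
k = 6. Exact enumeration is capped at k = 10 neighbors (far above any node
degree arising here); larger sets are rejected rather than approximated, so
a user is never served a silently degraded estimate.

Contributions are reported as raw variance shares (instrength of j sums to
the R² of j on its neighbors), not renormalized to sum to one. Percentages
are shares of variance, e.g. "SMA and PAS jointly account for 28% of the
variance in QoL".

The regressions use the sample correlation matrix of the analyzed data; the
GGM contributes only the neighbor sets. Directionality language here is
heuristic: a relative-importance edge i→j quantifies predictive
contribution, not causality, and the package takes no position beyond that.

## Stability machinery

Three layers, all deterministic given their seed:

- **Edge bootstrap** (`nonparametric_bootstrap()`): B resamples of n rows
  with replacement (B = 1000 by default for edge weights), the full
  estimator re-run on each, and 2.5%/97.5% empirical quantile intervals.
  Quantiles use type-7 interpolation so results are bit-reproducible.
  The per-statistic proportion of exact zeros is recorded — informative for
  model-selected edge weights, where a weak edge may be dropped in a
  sizeable fraction of resamples. Replicate-level failures are tolerated to
  5% of B and counted; beyond that the run aborts.
- **Paired difference tests** (`bootstrap_difference_test()`): per-replicate
  differences between two statistics *from the same resamples*, with a
  quantile interval; significance = zero outside the interval. Pairing is
  required by construction: both statistics must come from one bootstrap
  object. (Whether strength-sum comparisons should reuse the edge
  bootstrap's resamples was an open choice; paired resamples are the only
  construction under which the described difference interval is valid, so
  the package only offers that.)
- **Case-dropping stability** (`case_dropping_cs()`): for each drop
  proportion q in {0.1, …, 0.7, 0.75}, B subsamples of ⌈(1−q)·n⌉ rows
  without replacement, the full pipeline (structure selection → relative
  importance → strengths) re-estimated on each, and the Pearson correlation
  across nodes between subsample and full-sample strengths recorded. The CS
  coefficient is the largest q at which the 5% quantile of these
  correlations still reaches 0.7 — "with 95% certainty the correlation stays
  at least 0.7". The grid tops out at 0.75: beyond that the subsamples of a
  six-variable problem become small enough that re-selection noise, not the
  statistic's stability, dominates. B defaults to 100 for case-dropping
  (each replicate is a full re-estimation) versus 1000 for plain edge
  bootstraps.

## The synthetic-data generator

Cohort data of this kind are not publicly shareable, so the package carries
a generating model instead of a dataset. `reference_network_spec()` encodes
the published six-node network — seven partial correlations (QoL–SMA 0.39,
QoL–PAS 0.15, BC–SMA 0.31, PAS–SMA 0.29, BC–PAS 0.14, SMA–PHY 0.18, BC–PHY
−0.09), the stringency index isolated, zeros elsewhere (the sparsest model
consistent with the published structure) — together with the reported
per-variable means and SDs and n = 1392. `implied_covariance()` inverts the
partial-correlation map exactly (round-trip verified to 1e-8), and
`generate_dataset()` draws multivariate-normal samples from it.

What the generator emulates, and what it does not:

- **Emulated:** the conditional-dependence structure and edge weights, the
  marginal means/SDs, the right skew and gross-outlier contamination of the
  activity score (opt-in), and item-level Likert responses consistent with
  each instrument's scoring rules (opt-in, for exercising the scoring
  module).
- **Not emulated:** non-Gaussian dependence (tail dependence, nonlinear
  relations), measurement non-invariance, temporal policy dynamics behind
  the stringency index, and the facet-level (11- and 15-node) networks,
  whose edge weights were never published in full — requesting those
  fixtures raises an explicit "partial information only" error rather than
  inventing numbers. Passing tests therefore demonstrate correctness of the
  machinery under the stated generating model, not robustness to real-data
  pathologies.

Physical-activity realism settings were fixed once, by design rather than
fitting: the skew transform is the monotone map z ↦ (e^{λz} − 1)/λ with
λ = 0.15 applied to the bulk truncated at ±2 SD, then rescaled to the target
mean and SD. Truncation mirrors the bounded observed range of a weekly
MET-minute score, and the (λ, truncation) pair is chosen so the clean skewed
bulk stays strictly inside the 2.5 robust-SD MAD fence — making "the filter
removes exactly the injected outliers" a well-posed contract. Gross outliers
are injected at a 7.2% rate (the share of participants such a robust
pre-screen removes in cohorts of this kind) at ≥ 6 SDs above the mean,
positive-side only, as implausibly large activity totals are the realistic
failure mode. Injected rows are flagged in an attribute so tests can check
exact recovery.

## Scoring module decisions

Several instrument details are under-documented in the field and were
settled explicitly; each is a function argument, not a hard-coded guess:

- **Reverse coding** uses x ↦ 6 − x on the 1–5 scale. The default
  reverse-item set (`whoqol_default_reverse_items()`) covers all four
  death-and-dying items plus the negatively phrased sensory items 1–3 and
  autonomy item 1 in the fixed facet-grouped ordering; translations differ,
  so the set is a parameter of `score_whoqol()`.
- **Quality-of-life total** ranges 24–120 (24 items × 1–5); facets 4–20.
- **SMAS self-efficacy items** are treated as six response options recoded
  0–5 (their printed anchors run 0 to 5, which is internally inconsistent
  with a "5-point" label); `smas_default_options()` makes the counts
  overridable per administration.
- **PASS z-normalization** is computed within the analysis sample (no
  reference population exists for the scale); the normalization constants
  are returned so later participants can be scored on the same scale via
  `apply_pass_norms()`.
- **Activity durations** are interpreted as minutes per week: a mean
  MET-weighted score in the thousands is consistent with MET·minutes, not
  MET·hours.

The robust filter (`mad_outlier_mask()`) uses the normal-consistency
constant 1.4826 and a two-sided threshold of 2.5 robust SDs, applied to the
activity score only but dropping whole participants — filtering precedes
every estimation step, and the run report records counts before and after.
A zero MAD with non-constant data is an error (the robust scale is
undefined), not a silent keep-all.

## Problem sizes and runtime envelope

The test suite and the reproduction script work at the study's own scale:
100 simulated cohorts of n = 1392 for edge and strength recovery, and a
case-dropping analysis with B = 100 full pipeline re-estimations at each of
eight drop proportions. The compiled constrained-ML core makes a full
six-node structure search take a few tens of milliseconds, so the entire
suite runs in well under a minute on one CPU. Oracle-equivalence tests
(numeric-optimizer ML fits, exhaustive structure enumeration, ordering-level
LMG enumeration) are kept at 3–7 variables where the oracles are exact and
cheap.

## Known limitations

- Cross-sectional data: directed relative-importance edges are predictive
  decompositions, not causal effects.
- Pearson-only correlations; no polychoric or mixed-data variant.
- Exact LMG only (cap k = 10); no sampling approximation for high-degree
  nodes.
- The generator's Gaussian copula cannot express the full range of
  real-data misbehavior; stability results on synthetic data are
  best-case.
- Only the six-node generating model ships; facet-level networks cannot be
  reconstructed from published information.
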