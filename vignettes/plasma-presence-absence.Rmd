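---
title: "Presence/absence plasma proteomics and stability-selected BMI prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Presence/absence plasma proteomics and stability-selected BMI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Shotgun proteomics of depleted blood plasma yields, per sample, a list
of confidently identified proteins. Discarding abundance and keeping
only identity gives a binary sample-by-protein *presence/absence*
matrix — a representation that is robust across acquisition protocols
but statistically unusual: every feature is a 0/1 column. This package
implements a complete desk-side workflow over such matrices for
obesity cohorts stratified into five BMI groups (NORM, OW, OB1, OB2,
OB3, using half-open WHO-style cut-points at 25, 30, 35 and 40
kg/m²): catalog filtering, clustering of clinical and proteomic
profiles, discriminative pattern extraction, and sparse BMI
prediction. Because clinical cohort data cannot be shipped, a
synthetic-cohort generator with known ground truth accompanies every
stage; all quantitative statements below are computed by the package's
tests and analysis scripts, not transcribed from elsewhere.

```{r, eval = FALSE}
library(plasmapattern)
report <- run_pipeline(pipeline_config(seed = 1))
```

## The synthetic cohort generator

`simulate_cohort()` draws, per group, BMI from a *range-truncated*
normal, height and age from normals, and sex from the group's female
fraction. Group sizes (22/21/19/21/21), BMI means/sds, age, height and
sex ratios default to the published characteristics of a 104-subject
obesity cohort. Weight is **derived** as `bmi * (height/100)^2` rather
than drawn, so BMI consistency is exact by construction and the
group-mean weight emerges as `E[BMI]·E[(h/100)²]` (about 64.9 kg for
the NORM group, within 0.05 kg of the published 64.93 because height
variance enters through `E[h²]`).

Calibration of the truncated normal matters: naively truncating a
normal with the target moments shifts both. `calibrate_truncated_normal()`
solves the two-moment matching problem numerically and refuses
infeasible targets. An important subtlety discovered during
development: a truncated normal on a finite range can never exceed the
sd of the uniform distribution on that range (the log-concave
limit). The empirical sds of the NORM (1.90 on a width-6.5 range,
limit ≈ 1.876) and OB1 (1.69 on width 5, limit ≈ 1.443) strata exceed
that limit — real BMI within strata is more edge-heavy than any
truncated Gaussian. The generator therefore uses
`nearest_truncated_normal()`: the group *mean* is matched exactly (it
drives everything downstream — group labels, weight, effect
standardisation) and the sd is taken as close to the target as the
family allows, with the underlying sigma capped at 100 so the
inverse-CDF sampler stays well conditioned. This is a deliberate
modelling choice of the package, stated here rather than hidden.

The proteome model is logistic in standardised BMI: protein *j* is
present in sample *i* with probability
`plogis(a_j + b_j * z_i)`, `z_i = (BMI_i - 30) / 6`. The
standardisation constants are fixed, not per-cohort statistics, so an
effect size `b = 3` means the same thing in any simulation. Defaults:
15 informative proteins with slope magnitudes spaced over [1, 3] and
alternating sign (mirroring the scale of published discriminative
patterns), 75 pure-noise proteins with baseline logits uniform on
[-2, 2], 5 ubiquitous proteins (logit +10, presence probability
> 0.999) and 10 "singleton-ish" proteins with expected occurrence of
one sample — the last two classes exist purely to exercise the
filters. Clinical parameters are linear in centred BMI plus Gaussian
noise; two (sodium, TSH) have zero slope and act as negative controls
for the screening step.

What the generator does *not* emulate: protein-protein occurrence
correlations (columns are conditionally independent given BMI),
abundance information, batch or protocol effects, and the
metabolically-healthy/unhealthy phenotype axis that motivates the
clinical question. Passing tests therefore demonstrate correctness of
the machinery and recoverability of BMI-linked occurrence signal, not
biological validity on real plasma.

## Filtering and catalog summaries

`filter_proteins()` drops columns identified in at most one sample
(unrepresentative; zero-occurrence columns of externally supplied
matrices are treated the same way) and columns identified in every
sample (non-specific — a column of ones carries no contrast for
clustering or regression). The operation is idempotent and after it
every column count c satisfies `2 <= c <= n - 1`. Because occurrence
counts change when samples are removed, `subset_samples()` re-applies
the filter after group exclusion by default (exposed as `refilter`).

## Clustering and partition agreement

Clinical profiles are clustered on column z-scores (sample sd, n−1)
with Euclidean distance; proteomic profiles with Jaccard distance
(`1 − |x∧y|/|x∨y|`, two empty profiles at distance 0 by convention).
Both use Ward linkage in the "D2" dialect — the Lance–Williams
recurrence applied to squared distances with heights reported on the
distance scale — which preserves Ward's variance interpretation for
Euclidean input; the unsquared "D" update is selectable because
analysis environments differ in their default. Agreement between a
flat cut of the dendrogram and the BMI-group labels is scored by the
Adjusted Rand Index from the partition contingency table, with the
degenerate 0/0 case (both partitions single-class or both all
singletons) defined as 1.

The discriminative pattern of the high-BMI sample cluster (the k = 2
cut member with larger mean BMI) is extracted by per-protein two-sided
Fisher exact tests on presence × membership, Benjamini–Hochberg
adjusted across proteins, keeping adjusted p ≤ 0.05 and ranking by
absolute prevalence difference. This is a reproducible surrogate for
reading patterns off a clustered heatmap; published analyses of this
kind rarely state a formal extraction rule, so the Fisher/BH procedure
is this package's own definition. The cluster-vs-complement BMI
contrast uses a two-sided Mann–Whitney U test (Welch t as an
alternative), and group screening of clinical parameters uses
Kruskal–Wallis (one-way ANOVA as an alternative) — robust defaults
chosen because no distributional claims are warranted for 5 small
strata; a parameter identical in every sample is reported with p = 1.

## The sparse BMI predictor

The core estimator minimises
`(1/2n)·Σ(y_i − β₀ − x_iβ)² + λ·Σ|β_j|` by cyclic coordinate descent
(compiled, covariance updates with a maintained gradient vector and
active-set iteration; convergence when the largest standardised-scale
coefficient change falls below 1e-7). Features are centred and scaled
by the population sd before penalisation — with 0/1 features this
equalises the penalty across prevalences — and coefficients are
reported back on the 0/1 scale. Correctness is pinned by
soft-threshold closed forms, OLS equivalence at λ = 0, exact nulling
at λ ≥ λ_max, KKT residual checks and an independent-implementation
cross-check.

λ is chosen on a 100-point log-spaced grid from λ_max down to
0.01·λ_max by repeated cross-validation (10 runs of 10-fold by
default), pooling out-of-fold squared errors across all folds and
repeats and taking the minimiser, ties resolved toward the larger
(sparser) λ. The CV criterion is mean squared error by default (mean
absolute error selectable). Fold fits run at tolerance 1e-5 — the CV
error curve is flat at that resolution — while reported models use
1e-7.

Stability selection repeats the whole procedure 10 times on random
90% subsamples drawn without replacement; the consensus panel is the
*intersection* of the 10 per-iteration selections, refit on all
samples with a freshly cross-validated λ (OLS refit selectable). An
empty consensus falls back to an intercept-only model, flagged. Model
error is the median absolute error (MAE) in kg/m², reported under two
protocols because published MAEs of this design rarely state which was
used: `holdout_pooled` (each iteration's model predicts its ~10%
held-out samples; all pairs pooled — the headline number) and
`refit_insample` (the consensus refit's training error, optimistic by
construction, which the tests confirm on average).

## Numerical and design choices

- Group boundaries are half-open (`[18.5,25), [25,30), …, [40,∞)`) so
  every BMI maps to exactly one group; BMI below the 18.5 inclusion
  floor becomes `NA` with a warning rather than a silent group.
- Matrix columns are ordered lexicographically by accession;
  dendrogram and coordinate-descent tie-breaks are index-order; all
  randomness flows from explicit integer seeds (the pipeline derives
  per-stage seeds from one master seed, so toggling a stage never
  perturbs another).
- Zero-variance feature columns are dropped with a warning before
  penalised fitting; a constant response yields an intercept-only
  model; an all-constant clinical matrix is an error.
- Problem sizes used by the test suite: the recovery study runs 50
  replicate cohorts (104 samples, 100 proteins, 5 planted effects of
  slope 3) with 3 CV repeats per subsample; the null study runs 20
  stability replicates and 50 clustering replicates. The analysis
  scripts use the full 10-repeat CV protocol on single cohorts.

## Known limitations

Presence/absence discards abundance, so the predictor can only exploit
occurrence shifts; proteins whose abundance but not detectability
tracks BMI are invisible here. The Fisher/BH pattern rule and the
choice of k = 2 for the sample cut are analysis conventions, not
estimates. The simulator's conditional-independence assumption makes
feature selection easier than on real plasma, where co-identified
protein complexes correlate; recovery rates reported by the tests
should be read as upper bounds on real-data behaviour. Published
headline values tied to the original cohort's raw matrix (protein
counts, specific UniProt panels, MAE 5.1/3.2 kg/m²) are not
reproducible without reprocessing the deposited raw spectra, which is
outside this package's scope.
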