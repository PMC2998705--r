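---
title: "Transcriptional age grading: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptional age grading: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mozage)
```

## The problem

Only *Anopheles* females that survive the extrinsic incubation period of
*Plasmodium* (roughly 9–15 days) plus the pre-feeding period can transmit
malaria, so the age structure of a vector population is one of the most
sensitive components of vectorial capacity — and one of the hardest to
measure. `mozage` implements an age-grading approach based on transcripts
whose abundance changes predictably over adult life: a small qRT-PCR panel,
measured relative to a stable reference gene, is converted into an age
estimate per individual mosquito.

The package covers three stages: (1) screening age-informative transcripts
from a factorial microarray experiment, (2) fitting a multivariate
calibration model on individuals of known age, and (3) predicting the age
of new individuals with uncertainty. A synthetic-data module generates both
kinds of raw data with known ground truth; every claim the package makes
about its own accuracy is computed on such data by the test suite and by
`scripts/acceptance.R`, never asserted.

## Screening (microarray stage)

Raw one-colour fluorescence matrices (genes × arrays, both sexes at ages 0,
10, 20, 30 days) are processed with the standard chain: threshold to 1.0,
log2 transformation, 75th-percentile shift per array, and baseline
transformation to each gene's median. Genes are filtered on raw signal:
the cutoff is the pooled 20th percentile and a gene survives if it exceeds
the cutoff in at least one array (`min_arrays_above` exposes stricter
readings, since the one-line description of this filter in screening
software is ambiguous).

Each gene is then tested with a fixed-effects two-way ANOVA (age, sex,
age×sex). Balanced designs use the classical sums-of-squares decomposition,
vectorized across all genes; unbalanced designs fall back to per-gene
type-II tests (on balanced data all types coincide, so the distinction only
matters for rescued or partial designs). P-values are asymptotic from the F
distribution, and Benjamini–Hochberg adjustment is applied per effect
across genes — per-effect rather than joint adjustment is a deliberate
choice; the joint alternative can be had by adjusting the pooled p-vector
with `bh_adjust()` directly. Genes with no variation at all are defined to
return p = 1 for every effect, so degenerate probes can never be selected.

A transcript is *age-only* when `q_age ≤ 0.01` while `q_sex` and
`q_interaction` exceed 0.01. Candidates are age-only genes whose
profile-level correlation with age (Pearson correlation of the per-age
mean expression against age, one point per age class) is strictly above
0.8 (up-regulated) or strictly below −0.4 (down-regulated); the asymmetry
follows the screening protocol this reproduces. Fold change
(`2^(max − min)` of the per-age means) is annotated against the fourfold
threshold but is not a gate: in the original protocol large fold changes
received *attention*, they did not exclude genes.

## The qRT-PCR calibration model

Triplicate Ct values are averaged per (sample, gene); a replicate SD above
0.5 cycles raises a QC flag but never drops the sample. Expression is
normalized as a **logcontrast**: `x[i, g] = meanCt[i, g] − meanCt[i, ref]`,
with the 40S ribosomal protein S7 transcript (AGAP010592-RA) as reference.
Because Ct is, under full amplification efficiency, the negative log2 of
starting template, this difference is a log-scale contrast; no
amplification-efficiency correction is applied (none is available for this
assay), which is documented as an extension hook rather than hidden.
The logcontrast cancels any per-sample additive Ct shift — the invariance
the tests assert exactly — which is the point of reference-gene
normalization: input-amount and pipetting variation act approximately as
such shifts.

With age a univariate response, the first redundancy variate of a
canonical correlation analysis has a closed form: standardize each gene
column, regress centered age on the standardized matrix, and rescale the
fitted direction so the training variate has mean 0 and variance 1. The
achieved correlation is the multiple correlation R of age on the genes;
the tests verify this equivalence against `lm()` and `cancor()` to 1e-10.
Standardization is itself a modelling choice: the source protocol never
states whether gene measures were standardized, but "a larger absolute
loading means a more informative gene" is only meaningful on a common
scale, so loadings are reported for standardized values. Fitted values,
R² and predictions are invariant to that choice (and to any per-gene
affine re-expression, which is also asserted exactly).

The sign of the variate is fixed so that it correlates *positively* with
age, resolving an otherwise arbitrary ± ambiguity; the calibration line
`v = α + β·age` then has β > 0, and R² equals the squared canonical
correlation by algebra (asserted to 1e-10).

Degenerate geometry is handled deliberately: exactly collinear gene
columns (which arise in noise-free data, where every gene is a linear
function of age) are solved by SVD minimum-norm least squares with a
warning naming the dependent columns — the fitted variate is invariant to
which solution of the normal equations is taken, so nothing downstream
depends on the arbitrary part. Hard errors are reserved for constant ages,
constant gene columns, and data with no age association at all.

## Prediction and uncertainty

A new individual's age is the inverted calibration line,
`(v − α)/β`, returned unclipped: negative estimates near age zero are an
expected consequence of calibration error, not a bug, and truncating them
would bias population-level summaries.

Uncertainty comes from a nonparametric pairs bootstrap: training
individuals are resampled with replacement and the *entire* chain —
standardization constants, redundancy weights, calibration line — is
refitted per resample, since the quantity of interest is the age
prediction, not the line alone. By default
(`interval = "prediction"`) each replicate also draws one calibration
residual from the refitted model and perturbs the held-out score by it
before inversion. This makes the 95% percentile interval a *prediction*
interval: it represents the error of the age estimate itself, combining
model uncertainty with the individual-level spread around the calibration
line. The chain-only variant (`interval = "calibration"`) is available but
markedly under-covers the true age at n ≈ 34, because the held-out
individual's own biological noise — the dominant error source at this
sample size — is invisible to it. Both variants collapse to zero-width
intervals on noise-free data. The percentile interval (not BCa) is used;
no bias correction is part of the procedure being reproduced. The
predicted age is the median of the bootstrap distribution, which by
construction lies inside the percentile interval.

Validation is leave-one-out cross-validation: each individual is predicted
by a model trained on the others, with per-sample bootstrap seeds derived
deterministically from the master seed and the sample id so results are
identical under any sample ordering. `B = 0` gives fast plug-in-only
validation for property checks. Sexes are calibrated separately throughout
(the assay behaves differently in males); models carry a `sex_label`.

### The bias diagnostic and an inverse-regression caveat

`bias_diagnostic()` regresses signed LOOCV residuals on *predicted* age,
the conventional visual check. One caveat is worth stating precisely:
under a perfectly specified model this regression has positive expected
slope ≈ Var(error)/(Var(age) + Var(error)) (about 0.18 under the default
study conditions), because inverse-regression estimates spread beyond the
true age range — large predictions systematically overshoot and small ones
undershoot. A significant slope here is therefore *not* by itself evidence
of model misspecification. The regression of residuals on *true* age,
reported alongside when true ages are known, is free of the artefact and
is the cleaner null check; the test suite asserts both behaviours.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated, mirroring the laboratory design: ages 0, 5, …, 30 days
post-eclosion, five individuals per age × sex cell with one random female
dropped (n = 34 females, 35 males), triplicate Ct measurements over a
45-cycle assay, and a four-gene panel named after the assay transcripts.

For individual *i* with age *a*, replicate Ct values are

* reference: `ref_mu + b_i + technical noise`,
* gene *g*: `ref_mu + b_i + delta_g + slope_g·a + e_ig + technical noise`,

where `b_i ~ N(0, σ_bio²)` is a global per-individual shift shared by all
genes (laboratory input variation — it cancels in the logcontrast, which
is precisely why reference-gene normalization is used) and
`e_ig ~ N(0, σ_bio²)` is an individual-by-gene biological deviation, the
component that survives normalization and sets the between-individual
logcontrast spread.

Defaults were fixed once, by calculation rather than fitting: slopes
(−0.10, −0.08, +0.07, −0.06) cycles/day (up-regulated transcripts have
negative ΔCt slopes), `σ_technical = 0.2` cycles (a typical triplicate
replicate SD), and `σ_biological = 0.72` cycles chosen in closed form so
that the population calibration R² matches the female assay's ≈ 0.82.
With design-age variance `V_a = 100` day², logcontrast noise variance
`σ² = σ_bio² + 2σ_t²/3 = 0.545` cycles², and signal content
`t = V_a · Σ slope² / σ² = 100 × 0.0249 / 0.545 ≈ 4.57`, the population
multiple R² is `t/(1+t) ≈ 0.820`. At this noise level the closed-form
prediction-error SD is `sqrt(σ²/Σ slope²) ≈ 4.7` days, i.e. an expected
mean absolute LOOCV residual around 4 days — which is what the acceptance
run measures.

The microarray generator plants four gene classes on the log2 scale: a
monotone age trend of total span `effect_size` (2 = fourfold), a sex
offset, a sex-dependent age trend with opposite signs in the two sexes
(interaction without a marginal age effect), and null genes; raw signal is
`baseline_mu·2^(log2 signal)` with gene baselines spread uniformly over
2–10 log2 units. Per-cell replication is exposed as `n_reps` (default 3)
rather than guessing the original hybridization count, which the source
experiment does not state.

What the generator does *not* emulate — and hence what passing tests do
not show about field data: amplification-efficiency differences between
genes, probe-level microarray artefacts (flags, saturation, spatial
effects), age-dependent variance, batch and temperature effects, and any
systematic difference between laboratory-reared and wild mosquitoes.
Synthetic validation demonstrates that the *estimator* is correct and
well-calibrated under its stated model, not that the four-gene assay
generalizes to every field population.

## Numerical choices

* Exact least squares (normal equations with Cholesky, SVD minimum-norm on
  rank deficiency at relative tolerance 1e-10); no iterative optimizer.
* Quantiles use R's default definition (type 7) everywhere, including the
  percentile-shift normalization and bootstrap percentiles.
* Gene ranking breaks |loading| ties lexicographically by gene id, making
  `select_informative_genes()` fully deterministic.
* Degenerate bootstrap resamples (constant age, no age association,
  numerically zero slope) are rejected and redrawn with a logged count;
  more than 50% degenerate draws aborts with a data error.
* Calibration-slope invertibility tolerance: |β| > 1e-8 (the training
  variate has unit SD, so this is a relative scale).
* Seeds are kept below 2³¹; per-sample child seeds are a polynomial string
  hash of the sample id combined with the master seed.

## Known limitations

* **Loading-based gene selection is unstable at small n.** The assay
  panel's genes are mutually collinear (all correlated with age), so
  their partial coefficients split and, at n = 34, a null gene can
  outrank the weakest informative gene in |loading|. Recovery of a planted
  4-gene panel among 9 is reliable at n ≈ 140 but only partial at n = 34.
  Rankings from small studies should be treated as indicative, not final.
* The logcontrast uses mean Ct differences without efficiency correction;
  if per-gene efficiencies are available, correcting Ct values upstream of
  the package is the intended route.
* Prediction intervals are percentile bootstrap intervals; at n ≈ 34 they
  cover slightly below nominal (≈ 93–95% measured), which is typical of
  the percentile method at this sample size.
* The screening ANOVA assumes independent arrays; pooled-sample designs
  make the "n" of the screen the number of pools, not of mosquitoes.

## Problem sizes used in validation

The shipped validation uses the study-scale design throughout: n = 34
females per dataset, 4 genes, B = 200–500 bootstrap replicates, 50
simulated datasets for the parameter-recovery study, 200 out-of-sample
predictions for the coverage study, and 1000-gene arrays (100 age-only, 50
sex-only, 50 interaction planted) for the screening study. These sizes
give Monte-Carlo error comfortably smaller than the acceptance bands while
keeping a full run in the low minutes.

```{r, eval = FALSE}
# A complete worked run at the study scale
sim <- simulate_qpcr(qpcr_sim_config(seed = 1))
lc  <- logcontrast(aggregate_replicates(sim$ct))
fem <- sim$samples[sim$samples$sex == "F", ]
model <- fit_age_model(lc[fem$sample_id, ], fem$age_days, sex_label = "F")
report <- loocv(lc[fem$sample_id, ], fem$age_days, B = 500, seed = 1)
report
bias_diagnostic(report)$bias_slope
```
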