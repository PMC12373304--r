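---
title: "Deep phenotyping of pre-treatment EHR periods: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep phenotyping of pre-treatment EHR periods: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aompheno)
```

## The problem

Patients respond very unevenly to antiobesity medications (AOMs), and the
clinical context most relevant to treatment choice is the period just before
pharmacotherapy begins. Longitudinal electronic health records (EHR) chronicle
that period — lab and vital measurements, diagnosis categories, drug
exposures — but as extremely sparse, irregularly sampled multivariate time
series. `aompheno` implements a complete pipeline for phenotyping such
pre-treatment periods: it constructs continuous treatment sessions from raw
drug-exposure records, extracts a fixed-grid temporal tensor per
pre-treatment year, embeds each tensor with a decay-imputing recurrent
autoencoder, and clusters the embeddings with Gaussian mixtures. Because real
single-site EHR cohorts cannot be redistributed, the package ships a
synthetic OMOP-style generator with *planted* phenotype clusters, so every
stage is exercised and validated end to end without protected data.

## Treatment sessions from exposure records

A *treatment session* is a continuous period of exposure to generally the
same active ingredients. Records are merged greedily in chronological order
against the open session's reference state (the union of member ingredient
sets, the session start, and the latest member end). A record *B* joins when
any of three rules holds:

1. *B* has exactly the session's ingredient set and starts at most 40 days
   after the session's end;
2. *B* has a proper subset of the session's ingredients, is itself at most
   40 days long, and starts at most 40 days after the session's end;
3. *B* adds at least one new ingredient, starts within 40 days of the
   session's start, and is at most 40 days long.

Otherwise *B* opens a new session. Three readings were genuinely open and are
fixed as follows. The "gap" is `start_B − latest member end`, so overlapping
or abutting records always satisfy the gap condition. "Less ingredient" is
read as a *proper subset* of the session's ingredient union (continuation of
a regimen with a dropped component), not merely smaller cardinality. "Within
40 days of initiating" is measured from the session's start day. A record
comparison against the whole session state (rather than only the immediately
preceding record) is likewise a choice, not a derivation; the exhaustive
small-case oracle in the test suite pins the implemented semantics down
precisely. A session's end extends to the maximum member end, including
subset records that outlast the current end.

Short off-label exposures are handled before session building: an off-label
record shorter than 30 days with no same-ingredient record within 30 days of
its span is removed, since brief courses of these drugs are commonly
prescribed for unrelated indications. Sessions with an exposure length of at
least 112 days ("medium to long" exposure) are retained; a `strict_gt` flag
switches to a strictly-greater reading.

Each selected session yields one *pre-treatment period*: the 365-day window
ending the day before treatment starts, with the *index day* 4 days before
initiation (a lead time for final pre-treatment assessments). Normal-BMI
control periods are matched 1:1 greedily (seeded case order) on identical
gender, age within 1 year and anchor date within 365 days; greedy matching is
reproducible and fast, and the matched count — not an optimal assignment — is
the quantity of interest.

## The temporal tensor

Each period is sampled at 13 points, 30 days apart, the newest 5 days before
initiation (so its look-back interval covers days 35 to 5 before treatment)
and the oldest 365 days before. For each measurement feature and point, the
observations in the half-open look-back window `(t_k − 30, t_k]` are averaged
(averaging is symmetric and robust; the windows never double-count a day) and
z-scored with training statistics; the mask records presence. Diagnosis (CCS
category) channels are always-observed binaries — 1 when any qualifying
diagnosis falls in the window — so decay imputation applies only to
measurement channels. The time-since-observation matrix follows the standard
GRU-D recursion in units of the 30-day spacing: 0 at the first step, 1 when
the previous step was observed, otherwise the previous value plus 1 (a
feature observed only at the oldest point therefore reaches 360/30 = 12 at
the newest). Carry-forward values start "cold" at the window edge: before a
feature's first in-window observation the last-observed value is the
feature's empirical mean, so imputation degenerates gracefully to the mean.
Events before the window do not inform the tensor; age/demographic channels
are not included by default (the explored features are measurements and CCS
categories).

*Data quality* of a period is the mean, over the 13 points, of the fraction
of measurement channels observed — a scalar in [0, 1]. Quality quartiles are
always computed on the current run's case population, never frozen: the
median of a real cohort (a few percent observed) is data-specific.

## The decay-imputing recurrent autoencoder

Missing inputs are imputed per feature *d* and step *t* as

x̂ = m·x + (1 − m)·(γ·x′ + (1 − γ)·x̃),  γ = exp(−max(0, W_γ δ + b_γ)),

where x′ is the last observed value, x̃ the feature's empirical training
mean, and δ the time since the last observation. When an observation is
recent γ ≈ 1 and the imputation carries the last value forward; as δ grows γ
decays toward 0 and the imputation *decays to the mean*. The input-decay
weights W_γ are constrained diagonal (one independent decay per feature).
Hidden-state decay — part of the original GRU-D design — is included and on
by default (`hidden_decay = FALSE` disables it); with it the previous hidden
state is shrunk by a learned function of δ before entering the gates.

The encoder runs 13 gated-recurrent steps over (x̂, m); the final hidden
state h_T (the bottleneck, default 120 units; the synthetic benchmark uses
16) is the period's dense embedding. The decoder is a plain GRU initialized
with h_T, unrolled 13 steps with zero inputs and a linear readout — the
minimal reading of "passing the bottleneck to a native recurrent decoder".
The loss is the sum of squared differences between the reconstruction and
the *post-imputation* inputs. Because the targets themselves depend on
trainable imputation parameters, the model could exploit a shortcut and bend
the imputation toward whatever the decoder happens to produce; by default
the targets are therefore detached from the gradient (`detach_targets =
FALSE` restores the faithful-but-unstable variant). Both the detached and
non-detached gradients are verified against numerical differentiation in the
test suite.

Training uses Adam (learning rate 1e-3, batch 64), early stopping on a
training-loss plateau (patience 10 epochs), and 5-fold cross-validation with
folds grouped by patient, so that a patient with several periods never
straddles the train/test divide (per-period folding is available via
`fold_by = "period"`). All randomness — fold split, initialization, batch
order — is governed by one integer seed, and runs are single-threaded
deterministic. The gradients are hand-derived backpropagation through time
in plain matrix code; there is no external deep-learning dependency.

The static baseline (`train_sae`) embeds the *static transformation* of each
period — the last observed value of each feature within the year, 0 with a
zero mask when never observed — with a dense autoencoder whose squared-error
loss is summed only over observed cells. It shares the temporal model's fold
assignments, making the two paths directly comparable.

## PCA, quality filtering, and mixture clustering

Principal components are fit on *training-fold* embeddings only (centered
eigendecomposition) and the eigenvectors applied to training and test
embeddings alike; the top 40 PCs feed clustering (when the bottleneck is
smaller than 40, all components are used). Periods below the population
median quality are removed first — low-quality periods cluster by
documentation intensity rather than physiology; ties at the median are
retained (the conservative reading of removing the bottom two quartiles).
Gaussian mixtures are fit over a candidate range of component counts
(default 1–15) and a small covariance-family set via `mclust`, selected by
BIC; the full selection trace is always kept, since a real cohort's "at
least K clusters" may reflect either a criterion optimum or a search cap.
Responsibilities are hardened by maximum responsibility (ties to the lowest
index). Cluster profiles report CCS prevalence (any qualifying diagnosis
within 365 days before the index day), mean z-scored most-recent
measurements in the same window, and per-feature presence rates, with
heatmap orderings by complete-linkage hierarchical clustering on Euclidean
distances. Two-dimensional coordinates for visualization come from the top
two PCs or from an exact (quadratic-cost) t-SNE implemented in-package;
t-SNE is never used for clustering or quantitative claims.

In `run_all`, the z-scoring statistics are fit once on the full case
population rather than per fold: they are first and second moments pooled
over thousands of observations, essentially identical across folds, while
the leakage-sensitive steps — autoencoder training and PCA — remain strictly
fold-disciplined. `fit_normalizer` itself only ever sees the period table it
is given, so per-fold normalization is available to callers who want it.

## The synthetic generator and what it does (not) show

The generator emulates the study conditions the pipeline targets: each
patient receives one or two planted treatment sessions of 120–400 days
(always in the medium/long class), realized as exposure records that
exercise every merge rule — same-ingredient continuations with gaps of 0–40
days, short proper-subset records, short add-on records within 40 days of
session start — plus occasional isolated sub-30-day off-label records that
the filter must remove. Planted sessions are exactly recoverable by the
cohort stage, which the tests assert across seeds. Phenotypes are planted as
per-feature latent means (±2 z-units by default, the separation used in the
standard benchmark), cluster-specific CCS prevalences (0.8 vs 0.1), and
optional linear drift; observed values add unit Gaussian noise. Presence is
Bernoulli per feature and window (default 0.5; real per-feature presence
spans roughly 5–90%), with a 2-fold boost in the window nearest treatment
start mirroring the pre-treatment documentation spike of real cohorts — the
boost applies only to the days −35 to −5 window. Measurement units are
omitted (features are born harmonized), since unit harmonization in practice
is manual curation, out of algorithmic scope.

The standard benchmark (`standard_benchmark_config`) uses 480 patients
(about 600 periods at the default second-session rate of 0.25), 15
measurement and 10 CCS channels, 4 phenotypes, bottleneck 16, 30 epochs and
5 folds. These sizes were chosen as the smallest configuration at which the
planted structure is comfortably in the regime the method assumes (hundreds
of periods per phenotype, multi-channel separation); the whole benchmark
runs in well under a minute on one CPU.

What passing tests show: the session rules, tensor construction, decay
equations, loss, gradients and model selection are implemented exactly as
specified, and the full pipeline recovers strong planted cluster structure
(adjusted Rand index well above 0.7 against planted labels, stable across
fold models) while the static baseline separates the same structure no
better than the temporal path. What they do not show: performance on real
EHR data, where missingness is informative in unknown ways (the generator
exposes only a flat rate plus the pre-index spike — the true mechanism is
not known), feature sets drift over years, units require curation, and
cluster counts are not planted. Conclusions about real cohorts require real
cohorts.

## Numerical choices and degenerate inputs

- Dates are integer day offsets from a fixed epoch; intervals closed on both
  ends unless stated (look-back windows are half-open). This removes
  calendar edge cases from the contracts.
- Zero-variance measurement features are dropped by the normalizer with a
  warning; never-observed features likewise.
- Multiple observations in one look-back window: averaged (measurements),
  OR-ed (diagnoses).
- Mixture fits fall back across covariance families via the selection
  criterion; responsibilities always renormalize to 1.
- Exact ties: quality at the median is retained; responsibility ties harden
  to the lowest cluster index.
- Determinism: every stochastic step takes a seed, and the temporary-seed
  helper restores the caller's RNG state, so library calls never perturb a
  user's session randomness. Run reports carry a structural hash of the full
  configuration.

## Known limitations

The package implements desk-scale analysis: single-threaded base-R matrix
training is adequate for bottlenecks of tens of units and thousands of
periods, not for cohorts of tens of thousands with hundreds of channels.
ICD-to-CCS mapping, RxNorm concept resolution and live OMOP connectivity are
out of scope — the generator emits CCS categories and ingredient keys
directly, and real extracts must be mapped upstream. Bariatric-surgery
exclusion is a patient flag, not derived logic. Year-over-year presence
trend testing and social-determinants comparisons are not implemented.
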