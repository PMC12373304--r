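# aompheno

Deep phenotyping of the pre-treatment year from longitudinal electronic
health records (EHR).

Obesity pharmacotherapy shows wide inter-individual response, which makes
phenotyping patients *before* an antiobesity-medication (AOM) course a
natural target for precision treatment. `aompheno` is an R implementation of
an EHR-based temporal deep-phenotyping pipeline for exactly that setting. It
is written for methods researchers and clinical informaticians who work with
OMOP-style longitudinal data: raw drug-exposure, measurement and diagnosis
tables go in; treatment sessions, pre-treatment temporal tensors, dense
period embeddings, mixture-model clusters and cluster profiles come out.
Since real single-site EHR data cannot be shared, the package also contains
a synthetic OMOP-style generator with planted phenotype clusters that
exercises every rule of the pipeline, so the whole method is testable and
reproducible on any machine.

## The method

**Treatment sessions.** Raw exposure records are merged into continuous
treatment sessions by gap rules: a record joins the open session if it (1)
has the identical ingredient set and starts ≤ 40 days after the session
ends, (2) has a proper subset of the ingredients with record length and gap
each ≤ 40 days, or (3) adds a new ingredient within 40 days of session start
with length ≤ 40 days. Short (< 30 day) isolated off-label records are
removed first; sessions of ≥ 112 days ("medium to long" exposure) are kept,
and each yields one 365-day pre-treatment period.

**Temporal tensor.** Each period is sampled at 13 points 30 days apart
(newest 5 days before initiation), giving per-feature values `x`, mask `m`
and time-since-last-observation `δ`.

**Decay-imputing recurrent autoencoder (GRU-D-AE).** Missing inputs are
imputed as

    x̂ = m·x + (1 − m)·(γ·x′ + (1 − γ)·x̃),   γ = exp(−max(0, W_γ δ + b_γ))

a trainable blend of the last observed value `x′` and the feature's
empirical mean `x̃` that *decays to the mean* as the observation gap grows.
A gated recurrent encoder over (x̂, m) produces the bottleneck embedding
`h_T`; a plain GRU decoder reconstructs the sequence, trained with the
squared-error loss `Σᵢ Σₜ (x̂ᵢₜ − x̄ᵢₜ)²` under 5-fold patient-grouped
cross-validation. Forward and backward passes are hand-written base-R
matrix code (no deep-learning framework), with gradients verified against
numerical differentiation.

**Clustering.** Train-fold PCA projects embeddings onto top principal
components (default 40); below-median-quality periods are removed; Gaussian
mixtures with BIC model selection (via `mclust`) cluster the scores; hard
labels come from maximum responsibility, and clusters are profiled against
diagnosis prevalence and z-scored recent measurements.

## Worked example

The standard synthetic benchmark plants 4 phenotypes (±2 z-units over 15
measurement channels, cluster-specific prevalence over 10 diagnosis
categories, 50% observation presence) in 480 patients and runs the entire
pipeline:

```r
library(aompheno)
report <- run_all(standard_benchmark_config(seed = 1))
print(report)
#> Phenotyping run 38fc0f3c
#>   simulate                480 ->   1128
#>   filter_oaom            1128 ->   1062
#>   sessions               1062 ->    613
#>   select_medium_long      613 ->    613
#>   periods                 613 ->    613
#>   featurize               613 ->    613
#>   train                   613 ->   3065
#>   cluster                 324 ->    324
#>   profile                 324 ->      4
#>   fold-1 planted-label ARI: 0.977
#>   mean cross-fold ARI:      0.969
#>   silhouette temporal/static: 0.857 / 0.580
```

Reading the stage counts: 480 patients produced 1128 raw exposure records;
66 short isolated off-label records were filtered; the remaining 1062
records merged into 613 treatment sessions (all medium/long here), hence 613
pre-treatment periods and tensors; training emitted embeddings from all 5
fold models (613 × 5 = 3065); the 324 at-or-above-median-quality periods
were clustered into 4 mixture components. The adjusted Rand index of 0.977
against the planted labels says the embedding + clustering path recovered
the planted phenotypes almost perfectly; the cross-fold ARI of 0.969 says
the five independently trained fold models agree on the labeling; and the
planted labels separate better in the temporal embedding's PC space
(silhouette 0.857) than in the static-baseline's (0.580) — the temporal path
earns its keep.

Individual stages are ordinary functions (`build_sessions`,
`derive_pre_aom_periods`, `build_tensor_set`, `train_grud_ae`, `fit_pca`,
`fit_gmm`, `profile_clusters`, ...) and accept plain data frames, so real
OMOP extracts can be fed in at any point.

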