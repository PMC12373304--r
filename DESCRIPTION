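Package: aompheno
Title: Deep Phenotyping of Pre-Treatment Periods from Longitudinal EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for electronic-health-record (EHR) based deep phenotyping of
    patients prior to antiobesity-medication (AOM) pharmacotherapy. Builds
    continuous treatment sessions from raw drug-exposure records using
    gap-based merge rules, derives 365-day pre-treatment observation windows,
    encodes sparse irregular clinical time series as fixed-grid temporal
    tensors (values, missingness mask, time-since-observation), embeds them
    with a gated-recurrent-unit autoencoder that imputes missing inputs by
    trainable decay toward the population mean (GRU-D), and clusters the
    resulting embeddings with principal components and Gaussian mixture
    models. Includes a synthetic OMOP-style EHR generator with planted
    phenotype clusters so the entire pipeline can be exercised and validated
    without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mclust
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
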