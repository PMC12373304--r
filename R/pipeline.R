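# End-to-end orchestration: simulate -> sessions -> featurize -> train ->
# cluster -> profile, with one configuration, fixed seeds and an evaluation
# report against the planted phenotype labels.

# Structural hash of a configuration (polynomial rolling hash over the
# serialized representation); recorded in the run report so artifacts from
# different configurations are distinguishable.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Configuration of a full pipeline run
#'
#' @param synth a [synth_config()].
#' @param train a [train_config()].
#' @param gap_days session-merge gap threshold (default 40).
#' @param oaom_min_days short off-label record threshold (default 30).
#' @param min_exposure medium/long exposure threshold in days (default 112).
#' @param strict_gt use strictly-greater-than for the exposure threshold.
#' @param n_pcs principal components used for clustering (default 40,
#'   capped at the bottleneck size).
#' @param k_range candidate mixture component counts (default 1:15).
#' @param quality_filter drop below-median-quality periods before
#'   clustering (default TRUE).
#' @param include_sae also run the static sparse-autoencoder baseline
#'   (default TRUE).
#' @param seed global seed for stages not covered by the sub-configs.
#' @return list of class `run_config` with a `hash` field.
#' @export
run_config <- function(synth, train = train_config(),
                       gap_days = 40L, oaom_min_days = 30L,
                       min_exposure = 112L, strict_gt = FALSE,
                       n_pcs = 40L, k_range = 1:15,
                       quality_filter = TRUE, include_sae = TRUE,
                       seed = 1L) {
  stopifnot(inherits(synth, "synth_config"), inherits(train, "train_config"))
  cfg <- list(synth = synth, train = train, gap_days = as.integer(gap_days),
              oaom_min_days = as.integer(oaom_min_days),
              min_exposure = as.integer(min_exposure),
              strict_gt = isTRUE(strict_gt), n_pcs = as.integer(n_pcs),
              k_range = as.integer(k_range),
              quality_filter = isTRUE(quality_filter),
              include_sae = isTRUE(include_sae), seed = as.integer(seed))
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' The package's standard synthetic benchmark configuration
#'
#' 480 patients (~600 pre-treatment periods at the default second-session
#' rate), 15 measurement and 10 CCS channels, 4 planted phenotypes at
#' +/- 2 z-units, presence 0.5, unit noise; bottleneck 16, 30 epochs,
#' 5 folds.
#'
#' @param seed integer seed.
#' @return a [run_config()].
#' @export
standard_benchmark_config <- function(seed = 1L) {
  run_config(
    synth = synth_config(n_patients = 480L, seed = seed),
    train = train_config(bottleneck = 16L, epochs = 30L, seed = seed),
    seed = seed)
}

stage <- function(report, name, n_in, n_out) {
  report$stages[[name]] <- list(stage = name, n_in = n_in, n_out = n_out)
  report
}

#' Run the full phenotyping pipeline on synthetic data
#'
#' Executes simulate, off-label filtering, session building, exposure
#' selection, period derivation, featurization, GRU-D autoencoder training,
#' per-fold PCA + quality filtering + GMM clustering, cluster profiling and
#' evaluation against the planted labels. Deterministic given the
#' configuration.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: stage row counts, the intermediate
#'   tables, per-fold losses, per-fold cluster labels, the mixture selection
#'   trace, planted-label metrics per fold, mean cross-fold label agreement
#'   (adjusted Rand index), silhouettes of the planted labels in temporal
#'   and static PC spaces, profiles for the first fold, and the config hash.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  report <- list(config = config, hash = config$hash, stages = list())

  sim <- simulate_ehr(config$synth)
  report <- stage(report, "simulate", config$synth$n_patients,
                  nrow(sim$drug_exposure))

  recs <- filter_oaom_records(sim$drug_exposure,
                              min_days = config$oaom_min_days)
  report <- stage(report, "filter_oaom", nrow(sim$drug_exposure), nrow(recs))

  sessions <- build_sessions(recs, gap_days = config$gap_days)
  report <- stage(report, "sessions", nrow(recs), nrow(sessions))

  selected <- select_medium_long(sessions, min_days = config$min_exposure,
                                 strict_gt = config$strict_gt)
  report <- stage(report, "select_medium_long", nrow(sessions), nrow(selected))

  periods <- derive_pre_aom_periods(selected)
  report <- stage(report, "periods", nrow(selected), nrow(periods))
  if (nrow(periods) == 0L)
    stop("run_all failed at stage 'periods': no sessions survived selection")

  # planted truth per period, via (person, session start)
  truth_key <- paste(sim$planted_sessions$person_id,
                     sim$planted_sessions$start_day)
  lab_key <- paste(sim$latent_labels$person_id, sim$latent_labels$session_idx)
  ps_lab <- sim$latent_labels$phenotype[
    match(paste(sim$planted_sessions$person_id,
                sim$planted_sessions$session_idx), lab_key)]
  planted <- ps_lab[match(paste(periods$person_id, periods$window_end),
                          truth_key)]

  feature_list <- list(
    meas = paste0("meas_", seq_len(config$synth$n_meas_features)),
    ccs = paste0("ccs_", seq_len(config$synth$n_ccs_features)))
  normalizer <- fit_normalizer(periods, sim$measurements, feature_list$meas)
  feature_list$meas <- normalizer$feature_ids
  tensors <- build_tensor_set(periods, sim$measurements, sim$diagnoses,
                              feature_list, normalizer)
  quality <- compute_quality_table(tensors)
  report <- stage(report, "featurize", nrow(periods),
                  dim(tensors$X)[1])

  fit <- train_grud_ae(tensors, config$train)
  report <- stage(report, "train", dim(tensors$X)[1],
                  nrow(fit$embeddings))

  keep_q <- if (config$quality_filter) filter_by_quality(quality)
            else quality
  hi <- match(keep_q$period_id, tensors$period_id)

  labels_by_fold <- list(); metrics_by_fold <- list()
  traces <- list(); pcs_by_fold <- list()
  for (k in seq_len(config$train$n_folds)) {
    emb <- embedding_matrix(fit, k)
    train_rows <- fit$fold != k
    pcm <- fit_pca(emb[train_rows, , drop = FALSE],
                   n_components_kept = config$n_pcs)
    scores <- project_pcs(emb, pcm)
    gmm <- fit_gmm(scores[hi, , drop = FALSE], k_range = config$k_range,
                   seed = config$seed + k)
    lab <- assign_clusters(gmm)
    labels_by_fold[[k]] <- data.frame(period_id = keep_q$period_id,
                                      fold_model = k, cluster = lab)
    metrics_by_fold[[k]] <- evaluate_against_truth(lab, planted[hi])
    traces[[k]] <- gmm$bic_trace
    pcs_by_fold[[k]] <- scores
  }
  report <- stage(report, "cluster", length(hi), length(hi))

  nf <- config$train$n_folds
  aris <- c()
  for (a in seq_len(nf - 1L)) for (b in (a + 1L):nf)
    aris <- c(aris, mclust::adjustedRandIndex(labels_by_fold[[a]]$cluster,
                                              labels_by_fold[[b]]$cluster))
  report$cross_fold_ari <- mean(aris)

  # silhouette of the planted labels in PC space (temporal vs static paths)
  report$silhouette_temporal <- mean_silhouette(planted[hi],
                                                pcs_by_fold[[1L]][hi, ])
  if (config$include_sae) {
    statics <- build_static_set(periods, sim$measurements, sim$diagnoses,
                                feature_list, normalizer)
    sae <- train_sae(statics, config$train, fold = fit$fold)
    semb <- sae$embeddings[sae$embeddings$fold_model == 1L, ]
    semb <- as.matrix(semb[, grep("^h_", names(semb))])
    spc <- fit_pca(semb[fit$fold != 1L, , drop = FALSE],
                   n_components_kept = config$n_pcs)
    sscores <- project_pcs(semb, spc)
    report$silhouette_static <- mean_silhouette(planted[hi], sscores[hi, ])
    report$sae_losses <- sae$losses
  }

  profiles <- profile_clusters(labels_by_fold[[1L]]$cluster, periods[hi, ],
                               sim$measurements, sim$diagnoses,
                               feature_list, normalizer)
  report <- stage(report, "profile", length(hi), length(profiles$clusters))

  report$sim <- sim
  report$periods <- periods
  report$planted <- planted
  report$quality <- quality
  report$retained_periods <- keep_q
  report$normalizer <- normalizer
  report$tensors <- tensors
  report$fit <- fit
  report$losses <- fit$losses
  report$labels_by_fold <- labels_by_fold
  report$metrics_by_fold <- metrics_by_fold
  report$selection_trace <- traces
  report$pc_scores <- pcs_by_fold
  report$profiles <- profiles
  report$ari <- metrics_by_fold[[1L]]$ari
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Phenotyping run", x$hash, "\n")
  for (s in x$stages)
    cat(sprintf("  %-20s %6d -> %6d\n", s$stage, s$n_in, s$n_out))
  cat(sprintf("  fold-1 planted-label ARI: %.3f\n", x$ari))
  cat(sprintf("  mean cross-fold ARI:      %.3f\n", x$cross_fold_ari))
  if (!is.null(x$silhouette_static))
    cat(sprintf("  silhouette temporal/static: %.3f / %.3f\n",
                x$silhouette_temporal, x$silhouette_static))
  invisible(x)
}

#' Evaluate cluster labels against planted phenotype labels
#'
#' Permutation-invariant agreement metrics between a clustering and the
#' generator's latent labels (synthetic runs only).
#'
#' @param labels integer cluster labels.
#' @param planted integer planted phenotype labels, same length.
#' @return list with `ari` (adjusted Rand index), `purity` (per-cluster
#'   majority fraction), `confusion` (cluster x phenotype table).
#' @export
evaluate_against_truth <- function(labels, planted) {
  stopifnot(length(labels) == length(planted))
  conf <- table(cluster = labels, phenotype = planted)
  list(ari = mclust::adjustedRandIndex(labels, planted),
       purity = apply(conf, 1L, function(r) max(r) / sum(r)),
       confusion = conf)
}
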