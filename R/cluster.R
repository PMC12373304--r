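# Clustering of period embeddings: train-fold PCA, quality filtering,
# Gaussian-mixture clustering with information-criterion model selection,
# cluster characterization, and 2-D visualization coordinates.

#' Fit PCA on training-fold embeddings
#'
#' Centered eigendecomposition of the training covariance; the eigenvectors
#' are later applied to training and test embeddings alike, so test data
#' never influences the model.
#'
#' @param train_embeddings n x H matrix of training-fold embeddings.
#' @param n_components_kept default number of components used downstream
#'   (default 40; capped at the available rank).
#' @return object of class `pc_model`: `rotation` (orthonormal columns,
#'   ordered by decreasing eigenvalue), `center`, `eigenvalues`,
#'   `n_components_kept`.
#' @export
fit_pca <- function(train_embeddings, n_components_kept = 40L) {
  if (nrow(train_embeddings) < 2L) stop("fit_pca: need >= 2 training rows")
  pr <- stats::prcomp(train_embeddings, center = TRUE, scale. = FALSE)
  structure(list(rotation = pr$rotation, center = pr$center,
                 eigenvalues = pr$sdev^2,
                 n_components_kept = min(n_components_kept, ncol(pr$rotation))),
            class = "pc_model")
}

#' Project embeddings onto principal components
#'
#' @param embeddings n x H matrix.
#' @param pc_model a [fit_pca()] result.
#' @param k number of components (default the model's
#'   `n_components_kept`).
#' @return n x k score matrix.
#' @export
project_pcs <- function(embeddings, pc_model, k = pc_model$n_components_kept) {
  k <- min(k, ncol(pc_model$rotation))
  sweep(as.matrix(embeddings), 2L, pc_model$center) %*%
    pc_model$rotation[, seq_len(k), drop = FALSE]
}

#' Filter periods by data quality
#'
#' Keeps periods whose quality is at or above the population median
#' (removing the 1st and 2nd quality quartiles; ties at the median are
#' retained).
#'
#' @param quality data.frame with `period_id` and `quality` (from
#'   [compute_quality_table()]).
#' @return the retained rows; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
filter_by_quality <- function(quality) {
  thr <- stats::median(quality$quality)
  out <- quality[quality$quality >= thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Fit a Gaussian mixture model with model selection
#'
#' Fits candidate component counts (and a small covariance-family set) by
#' expectation-maximization and selects the best model by the Bayesian
#' information criterion, via `mclust`. The full selection trace is kept.
#'
#' @param pc_scores n x k matrix of PC scores.
#' @param k_range candidate component counts (default 1:15).
#' @param seed integer seed for the (hierarchical-initialization) fit.
#' @param model_names mclust covariance families to try (default
#'   `c("EII", "VII", "EEE", "VVV")`).
#' @return object of class `gmm_model`: `K`, `model_name`, `weights`,
#'   `means`, `responsibilities` (rows sum to 1), `bic_trace`, and the
#'   underlying `mclust_fit`.
#' @importFrom mclust Mclust mclustBIC adjustedRandIndex
#' @export
fit_gmm <- function(pc_scores, k_range = 1:15, seed = 1L,
                    model_names = c("EII", "VII", "EEE", "VVV")) {
  pc_scores <- as.matrix(pc_scores)
  if (nrow(pc_scores) <= max(k_range))
    stop("fit_gmm: need more observations than the largest candidate K")
  fit <- with_seed(seed,
    mclust::Mclust(pc_scores, G = k_range, modelNames = model_names,
                   verbose = FALSE))
  if (is.null(fit)) stop("fit_gmm: mclust failed on all candidate models")
  z <- fit$z
  if (is.null(z)) z <- matrix(1, nrow(pc_scores), 1L)
  structure(list(K = fit$G, model_name = fit$modelName,
                 weights = fit$parameters$pro,
                 means = fit$parameters$mean,
                 responsibilities = z,
                 bic_trace = fit$BIC,
                 loglik = fit$loglik,
                 mclust_fit = fit),
            class = "gmm_model")
}

#' Harden mixture responsibilities into cluster labels
#'
#' @param gmm a [fit_gmm()] result (or any list with a `responsibilities`
#'   matrix).
#' @return integer label per period: the maximum-responsibility component,
#'   ties broken by the lowest cluster index.
#' @export
assign_clusters <- function(gmm) {
  apply(gmm$responsibilities, 1L, which.max)
}

#' Characterize clusters against diagnoses and measurements
#'
#' Per cluster: CCS prevalence (fraction of the cluster's periods with any
#' qualifying diagnosis within 365 days before the index day), the mean
#' z-scored most recent measurement values within that window, and
#' per-feature presence rates. Row/column orderings for heatmap export are
#' computed by complete-linkage hierarchical clustering with Euclidean
#' distance.
#'
#' @param labels integer cluster label per row of `periods`.
#' @param periods period data.frame (`period_id`, `person_id`,
#'   `index_day`).
#' @param measurements,diagnoses event tables.
#' @param feature_list list with `meas` and `ccs` vectors.
#' @param normalizer fitted [fit_normalizer()].
#' @return object of class `cluster_profiles`: matrices `prevalence`
#'   (clusters x CCS), `zmeans` (clusters x measurements), `presence`
#'   (clusters x features), `sizes`, and `row_order`/`col_order` lists.
#'   Empty clusters are excluded with a warning.
#' @export
profile_clusters <- function(labels, periods, measurements, diagnoses,
                             feature_list, normalizer) {
  stopifnot(length(labels) == nrow(periods))
  present <- sort(unique(labels))
  all_k <- seq_len(max(labels))
  if (length(setdiff(all_k, present)))
    warning("profile_clusters: empty cluster(s) excluded: ",
            paste(setdiff(all_k, present), collapse = ", "))
  nm <- length(feature_list$meas); nc <- length(feature_list$ccs)
  prevalence <- matrix(0, length(present), nc,
                       dimnames = list(paste0("cluster_", present),
                                       feature_list$ccs))
  zmeans <- matrix(NA_real_, length(present), nm,
                   dimnames = list(paste0("cluster_", present),
                                   feature_list$meas))
  presence <- matrix(0, length(present), nm + nc,
                     dimnames = list(paste0("cluster_", present),
                                     c(feature_list$meas, feature_list$ccs)))
  sizes <- integer(length(present))
  for (ci in seq_along(present)) {
    rows <- which(labels == present[ci])
    sizes[ci] <- length(rows)
    dxh <- matrix(0, length(rows), nc)
    zh <- matrix(NA_real_, length(rows), nm)
    for (j in seq_along(rows)) {
      p <- periods[rows[j], ]
      lo <- p$index_day - 365L
      dx <- diagnoses[diagnoses$person_id == p$person_id &
                      diagnoses$day > lo & diagnoses$day <= p$index_day, ,
                      drop = FALSE]
      dxh[j, ] <- as.numeric(feature_list$ccs %in% dx$ccs_id)
      me <- measurements[measurements$person_id == p$person_id &
                         measurements$day > lo &
                         measurements$day <= p$index_day, , drop = FALSE]
      for (d in seq_len(nm)) {
        ev <- me[me$feature_id == feature_list$meas[d], , drop = FALSE]
        if (nrow(ev))
          zh[j, d] <- normalize_values(ev$value[which.max(ev$day)],
                                       feature_list$meas[d], normalizer)
      }
    }
    prevalence[ci, ] <- colMeans(dxh)
    zmeans[ci, ] <- colMeans(zh, na.rm = TRUE)
    presence[ci, ] <- c(colMeans(!is.na(zh)), colMeans(dxh))
  }
  hc_order <- function(M) {
    M[is.na(M)] <- 0
    if (nrow(M) < 3L) list(rows = seq_len(nrow(M)), cols = seq_len(ncol(M)))
    else list(rows = stats::hclust(stats::dist(M), "complete")$order,
              cols = if (ncol(M) >= 3L)
                stats::hclust(stats::dist(t(M)), "complete")$order
              else seq_len(ncol(M)))
  }
  structure(list(clusters = present, sizes = sizes, prevalence = prevalence,
                 zmeans = zmeans, presence = presence,
                 prevalence_order = hc_order(prevalence),
                 zmeans_order = hc_order(zmeans)),
            class = "cluster_profiles")
}

#' Mean silhouette width of a labelling
#'
#' @param labels integer labels (at least two distinct values).
#' @param X coordinate matrix.
#' @return mean silhouette width over all points, computed from Euclidean
#'   distances.
#' @export
mean_silhouette <- function(labels, X) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(labels) == n, length(unique(labels)) >= 2L)
  DM <- as.matrix(stats::dist(X))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) sum(DM[i, own]) / (sum(own) - 1L) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(DM[i, labels == k]), 0))
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' 2-D t-SNE coordinates of PC scores
#'
#' Exact (quadratic-cost) t-distributed stochastic neighbor embedding with
#' per-point bandwidths calibrated to the target perplexity, early
#' exaggeration and momentum gradient descent. Used for visualization only,
#' never for clustering.
#'
#' @param pc_scores n x k score matrix; n must exceed `3 * perplexity`.
#' @param perplexity target perplexity (default 30).
#' @param seed integer seed (coordinates are deterministic given the seed).
#' @param max_iter gradient-descent iterations (default 500).
#' @return n x 2 coordinate matrix.
#' @export
tsne_embed <- function(pc_scores, perplexity = 30, seed = 1L,
                       max_iter = 500L) {
  X <- as.matrix(pc_scores)
  n <- nrow(X)
  if (n <= 3 * perplexity)
    stop("tsne_embed: need n > 3 * perplexity (n = ", n, ")")
  D2 <- as.matrix(stats::dist(X))^2
  logU <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 }
      else { p <- p / sp; H <- -sum(p[p > 0] * log(p[p > 0])) }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P[P < 1e-12] <- 1e-12
  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2L)
    inc <- matrix(0, n, 2L)
    for (it in seq_len(max_iter)) {
      ex <- if (it <= 100L) 4 else 1
      mom <- if (it <= 250L) 0.5 else 0.8
      sumY <- rowSums(Y^2)
      num <- 1 / (1 + outer(sumY, sumY, `+`) - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- num / sum(num)
      Q[Q < 1e-12] <- 1e-12
      L <- (ex * P - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      inc <- mom * inc - 200 * grad
      Y <- Y + inc
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    Y
  })
}
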