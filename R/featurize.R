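# Featurization: fixed 13-point sampling grid, temporal tensors
# (values / mask / time-since-observation), normalization statistics,
# data-quality scores, static transformation and presence rates.

GRID_POINTS <- 13L
GRID_SPACING <- 30L
GRID_LEAD <- 5L

#' Build the 13-point pre-treatment sampling grid
#'
#' Data points are sampled every 30 days over the 365-day pre-treatment
#' window with a maximum look-back of 30 days, giving 13 sampling points and
#' 12 intervals. The newest point sits 5 days before treatment initiation
#' (its look-back interval spans days 35 to 5 before initiation); the oldest
#' sits 365 days before.
#'
#' @param session_start_day integer day of treatment initiation.
#' @return object of class `sampling_grid`: list with `points` (13 absolute
#'   day offsets, ordered oldest to newest) and `lookback_days` (30).
#' @export
build_sampling_grid <- function(session_start_day) {
  pts <- session_start_day - GRID_LEAD - GRID_SPACING * ((GRID_POINTS - 1L):0L)
  structure(list(points = as.integer(pts), lookback_days = GRID_SPACING),
            class = "sampling_grid")
}

#' Fit normalization statistics on training-fold data
#'
#' Computes per-measurement-feature mean and standard deviation from the
#' observed values of the training periods only (events within the grid's
#' look-back coverage of each training window). Features with zero standard
#' deviation are reported and dropped. The empirical means of the normalized
#' training values (`xtilde`, the decay-to-mean target of the GRU-D
#' imputation) are also stored.
#'
#' @param train_periods data.frame of training periods (needs `person_id`,
#'   `window_end`).
#' @param measurements measurement event table (`person_id`, `feature_id`,
#'   `value`, `day`).
#' @param feature_ids character vector of measurement feature ids to fit.
#' @return object of class `normalizer`: list with `feature_ids` (retained),
#'   `mean`, `sd`, `xtilde` (all named by feature), `dropped`.
#' @export
fit_normalizer <- function(train_periods, measurements, feature_ids) {
  vals <- vector("list", length(feature_ids))
  names(vals) <- feature_ids
  for (j in seq_len(nrow(train_periods))) {
    grid <- build_sampling_grid(train_periods$window_end[j])
    lo <- grid$points[1] - grid$lookback_days
    hi <- grid$points[GRID_POINTS]
    sel <- measurements$person_id == train_periods$person_id[j] &
      measurements$day > lo & measurements$day <= hi &
      measurements$feature_id %in% feature_ids
    ev <- measurements[sel, , drop = FALSE]
    for (f in unique(ev$feature_id))
      vals[[f]] <- c(vals[[f]], ev$value[ev$feature_id == f])
  }
  mu <- vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 0)
  sdv <- vapply(vals, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0)
  drop <- feature_ids[is.na(mu) | sdv <= 0]
  if (length(drop))
    warning("fit_normalizer: dropping zero-variance or unobserved features: ",
            paste(drop, collapse = ", "))
  keep <- setdiff(feature_ids, drop)
  xtilde <- vapply(keep, function(f)
    mean((vals[[f]] - mu[f]) / sdv[f]), 0)
  structure(list(feature_ids = keep, mean = mu[keep], sd = sdv[keep],
                 xtilde = xtilde, dropped = drop),
            class = "normalizer")
}

#' Apply z-scoring to raw measurement values
#' @param values numeric vector of raw values.
#' @param feature feature id (single string).
#' @param normalizer a fitted [fit_normalizer()] object.
#' @return z-scored values.
#' @keywords internal
normalize_values <- function(values, feature, normalizer) {
  (values - normalizer$mean[[feature]]) / normalizer$sd[[feature]]
}

delta_recursion <- function(M) {
  # time since last observation in grid-spacing units; standard GRU-D
  # recursion: 0 at the first step, then 1 if the previous step was
  # observed, else previous delta + 1.
  T_ <- nrow(M); D <- ncol(M)
  Delta <- matrix(0, T_, D)
  if (T_ > 1L) for (t in 2:T_)
    Delta[t, ] <- ifelse(M[t - 1L, ] == 1, 1, Delta[t - 1L, ] + 1)
  Delta
}

#' Extract the temporal tensor of one pre-treatment period
#'
#' For each of the 13 sampling points and each measurement feature, takes the
#' mean of the observations inside the half-open look-back window
#' `(t_k - 30, t_k]` (z-scored via the normalizer) with mask 1, or mask 0
#' when the window holds no observation. CCS diagnosis channels are
#' always-observed binaries: 1 when any qualifying diagnosis falls in the
#' window, else 0. The time-since-observation matrix `Delta` follows the
#' GRU-D recursion in units of the 30-day grid spacing; `Xlast` carries the
#' last observed value forward (initialized at the feature's empirical mean
#' so pre-first-observation imputation falls back to the mean).
#'
#' @param period one-row data.frame (or list) with `person_id`,
#'   `window_end`.
#' @param measurements,diagnoses event tables.
#' @param feature_list list with character vectors `meas` and `ccs`.
#' @param normalizer fitted [fit_normalizer()] covering `feature_list$meas`.
#' @return list (class `temporal_tensor`) with 13 x D matrices `X`, `M`,
#'   `Delta`, `Xlast`, plus `meas_channels`, `ccs_channels`, `xtilde`
#'   (length-D decay-to-mean targets) and `channels` (column names).
#' @export
extract_temporal_tensor <- function(period, measurements, diagnoses,
                                    feature_list, normalizer) {
  unknown <- setdiff(feature_list$meas, normalizer$feature_ids)
  if (length(unknown))
    stop("extract_temporal_tensor: unknown feature id(s): ",
         paste(unknown, collapse = ", "))
  grid <- build_sampling_grid(period$window_end)
  Dm <- length(feature_list$meas); Dc <- length(feature_list$ccs)
  D <- Dm + Dc
  X <- matrix(0, GRID_POINTS, D)
  M <- matrix(0, GRID_POINTS, D)
  colnames(X) <- colnames(M) <- c(feature_list$meas, feature_list$ccs)
  me <- measurements[measurements$person_id == period$person_id, , drop = FALSE]
  dx <- diagnoses[diagnoses$person_id == period$person_id, , drop = FALSE]
  for (k in seq_len(GRID_POINTS)) {
    hi <- grid$points[k]; lo <- hi - grid$lookback_days
    win_me <- me[me$day > lo & me$day <= hi, , drop = FALSE]
    for (d in seq_len(Dm)) {
      f <- feature_list$meas[d]
      v <- win_me$value[win_me$feature_id == f]
      if (length(v)) {
        X[k, d] <- mean(normalize_values(v, f, normalizer))
        M[k, d] <- 1
      }
    }
    if (Dc) {
      win_dx <- dx[dx$day > lo & dx$day <= hi, , drop = FALSE]
      X[k, Dm + seq_len(Dc)] <- as.numeric(feature_list$ccs %in% win_dx$ccs_id)
      M[k, Dm + seq_len(Dc)] <- 1
    }
  }
  xtilde <- c(unname(normalizer$xtilde[feature_list$meas]), rep(0, Dc))
  # Xlast[k, ] holds the value available *entering* step k: an observation at
  # step k informs steps > k only; before the first observation it falls back
  # to the empirical mean.
  Xl <- matrix(rep(xtilde, each = GRID_POINTS), GRID_POINTS, D)
  for (d in seq_len(D)) {
    last <- xtilde[d]
    for (k in seq_len(GRID_POINTS)) {
      Xl[k, d] <- last
      if (M[k, d] == 1) last <- X[k, d]
    }
  }
  structure(list(X = X, M = M, Delta = delta_recursion(M), Xlast = Xl,
                 meas_channels = seq_len(Dm),
                 ccs_channels = if (Dc) Dm + seq_len(Dc) else integer(0),
                 xtilde = xtilde,
                 channels = c(feature_list$meas, feature_list$ccs)),
            class = "temporal_tensor")
}

#' Build the stacked tensor set for a period table
#'
#' @param periods data.frame of pre-treatment periods.
#' @param measurements,diagnoses event tables.
#' @param feature_list list with `meas` and `ccs` feature id vectors.
#' @param normalizer fitted [fit_normalizer()].
#' @return list (class `tensor_set`) of arrays `X`, `M`, `Delta`, `Xlast`
#'   with dim `c(n_periods, 13, D)`, plus `x_mean` (length-D decay targets),
#'   `period_id`, `person_id`, `meas_channels`, `ccs_channels`, `channels`.
#' @export
build_tensor_set <- function(periods, measurements, diagnoses,
                             feature_list, normalizer) {
  n <- nrow(periods)
  Dm <- length(feature_list$meas); D <- Dm + length(feature_list$ccs)
  arr <- function() array(0, c(n, GRID_POINTS, D))
  X <- arr(); M <- arr(); Delta <- arr(); Xlast <- arr()
  xtilde <- NULL; channels <- NULL; mc <- NULL; cc <- NULL
  for (i in seq_len(n)) {
    tt <- extract_temporal_tensor(periods[i, ], measurements, diagnoses,
                                  feature_list, normalizer)
    X[i, , ] <- tt$X; M[i, , ] <- tt$M
    Delta[i, , ] <- tt$Delta; Xlast[i, , ] <- tt$Xlast
    if (is.null(xtilde)) {
      xtilde <- tt$xtilde; channels <- tt$channels
      mc <- tt$meas_channels; cc <- tt$ccs_channels
    }
  }
  structure(list(X = X, M = M, Delta = Delta, Xlast = Xlast,
                 x_mean = xtilde, period_id = periods$period_id,
                 person_id = periods$person_id,
                 meas_channels = mc, ccs_channels = cc, channels = channels),
            class = "tensor_set")
}

#' Data quality of a pre-treatment period
#'
#' Quality is the average, over the 13 sampling points, of the proportion of
#' measurement channels observed — a scalar in `[0, 1]`.
#'
#' @param tensor a [extract_temporal_tensor()] result (or any list with `M`
#'   and `meas_channels`).
#' @return numeric scalar in `[0, 1]`.
#' @export
compute_quality <- function(tensor) {
  mean(tensor$M[, tensor$meas_channels, drop = FALSE])
}

#' Quality scores and quartile labels for a period population
#'
#' @param tensor_set a [build_tensor_set()] result.
#' @return data.frame `period_id`, `quality`, `quartile` (1 = lowest);
#'   quartiles are computed over the supplied population, not frozen
#'   constants.
#' @export
compute_quality_table <- function(tensor_set) {
  n <- dim(tensor_set$M)[1]
  q <- vapply(seq_len(n), function(i)
    mean(tensor_set$M[i, , tensor_set$meas_channels]), 0)
  br <- stats::quantile(q, c(0.25, 0.5, 0.75))
  data.frame(period_id = tensor_set$period_id, quality = q,
             quartile = 1L + (q > br[1]) + (q > br[2]) + (q > br[3]))
}

#' Static transformation of a pre-treatment period
#'
#' Extracts, per feature, the last observed value within the 365-day window
#' `[window_start, window_end)`; features never observed are imputed with 0
#' and flagged by a 0 mask so they can be excluded from the reconstruction
#' loss. CCS channels are the binary any-occurrence indicator with mask 1.
#'
#' @inheritParams extract_temporal_tensor
#' @return list (class `static_vector`) with `values` (length D) and `mask`.
#' @export
static_transform <- function(period, measurements, diagnoses,
                             feature_list, normalizer) {
  Dm <- length(feature_list$meas); Dc <- length(feature_list$ccs)
  values <- numeric(Dm + Dc); mask <- numeric(Dm + Dc)
  lo <- period$window_end - 365L
  me <- measurements[measurements$person_id == period$person_id &
                     measurements$day >= lo &
                     measurements$day < period$window_end, , drop = FALSE]
  for (d in seq_len(Dm)) {
    f <- feature_list$meas[d]
    ev <- me[me$feature_id == f, , drop = FALSE]
    if (nrow(ev)) {
      last <- ev[which.max(ev$day), ]
      values[d] <- normalize_values(last$value, f, normalizer)
      mask[d] <- 1
    }
  }
  if (Dc) {
    dx <- diagnoses[diagnoses$person_id == period$person_id &
                    diagnoses$day >= lo &
                    diagnoses$day < period$window_end, , drop = FALSE]
    values[Dm + seq_len(Dc)] <- as.numeric(feature_list$ccs %in% dx$ccs_id)
    mask[Dm + seq_len(Dc)] <- 1
  }
  structure(list(values = values, mask = mask,
                 channels = c(feature_list$meas, feature_list$ccs)),
            class = "static_vector")
}

#' Static vectors for a period table
#' @inheritParams build_tensor_set
#' @return list with matrix `values` (n x D), matrix `mask`, `period_id`,
#'   `person_id`.
#' @export
build_static_set <- function(periods, measurements, diagnoses,
                             feature_list, normalizer) {
  n <- nrow(periods)
  D <- length(feature_list$meas) + length(feature_list$ccs)
  V <- matrix(0, n, D); K <- matrix(0, n, D)
  for (i in seq_len(n)) {
    sv <- static_transform(periods[i, ], measurements, diagnoses,
                           feature_list, normalizer)
    V[i, ] <- sv$values; K[i, ] <- sv$mask
  }
  list(values = V, mask = K, period_id = periods$period_id,
       person_id = periods$person_id)
}

#' Feature presence rates over 30-day windows around treatment start
#'
#' Computes, for each feature and each of the 24 consecutive 30-day
#' intervals surrounding treatment initiation (12 before and 12 after the
#' pre-treatment grid's newest point, i.e. from day -395 to day +325
#' relative to the session start, labelled by the interval's newest day
#' relative to start), the fraction of periods with at least one event of
#' that feature in the interval.
#'
#' @param periods period data.frame (`person_id`, `window_end`).
#' @param measurements,diagnoses event tables.
#' @param feature_list list with `meas` and `ccs` vectors.
#' @param n_before,n_after number of 30-day intervals before/after the
#'   newest pre-treatment point (defaults 12 and 12).
#' @return matrix features x windows of rates in `[0, 1]`; column names give
#'   the window's day range relative to treatment start.
#' @export
compute_presence_rates <- function(periods, measurements, diagnoses,
                                   feature_list, n_before = 12L, n_after = 12L) {
  feats <- c(feature_list$meas, feature_list$ccs)
  offs <- (-(n_before):(n_after - 1L)) * GRID_SPACING  # newest day of window,
  # relative to (start - 5)
  rates <- matrix(0, length(feats), length(offs), dimnames = list(
    feats, paste0("(", offs - GRID_SPACING - GRID_LEAD, ",",
                  offs - GRID_LEAD, "]")))
  n <- nrow(periods)
  for (i in seq_len(n)) {
    anchor <- periods$window_end[i] - GRID_LEAD
    me <- measurements[measurements$person_id == periods$person_id[i], , drop = FALSE]
    dx <- diagnoses[diagnoses$person_id == periods$person_id[i], , drop = FALSE]
    for (w in seq_along(offs)) {
      hi <- anchor + offs[w]; lo <- hi - GRID_SPACING
      fm <- unique(me$feature_id[me$day > lo & me$day <= hi])
      fc <- unique(dx$ccs_id[dx$day > lo & dx$day <= hi])
      rates[, w] <- rates[, w] + (feats %in% c(fm, fc))
    }
  }
  rates / max(n, 1L)
}
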