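# GRU-D autoencoder (decay-to-mean input imputation, recurrent encoder,
# bottleneck, recurrent decoder, squared-error reconstruction loss) and the
# static sparse-autoencoder baseline, trained with hand-derived analytic
# gradients (backpropagation through time) and Adam.
#
# Batch convention: time-step slices are N x D (samples x channels) or
# N x H matrices; full inputs are [N, T, D] arrays.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Trainable decay weight gamma
#'
#' `gamma = exp(-max(0, W_gamma * delta + b_gamma))`, elementwise: the weight
#' placed on the last observed value when imputing a missing input. `gamma`
#' is 1 at `delta = 0` (with zero bias) and decays toward 0 as the time since
#' the last observation grows, shifting the imputation toward the empirical
#' mean ("decay to mean").
#'
#' @param delta non-negative time since last observation (scalar, vector, or
#'   N x D matrix in grid-spacing units).
#' @param W_gamma per-feature decay weights (scalar or length-D vector).
#' @param b_gamma per-feature decay bias (scalar or length-D vector).
#' @return gamma in `(0, 1]`, same shape as `delta`.
#' @export
decay_weight <- function(delta, W_gamma, b_gamma = 0) {
  if (any(delta < 0)) stop("decay_weight: delta must be non-negative")
  if (is.matrix(delta)) {
    s <- sweep(delta, 2L, rep_len(W_gamma, ncol(delta)), `*`)
    s <- sweep(s, 2L, rep_len(b_gamma, ncol(delta)), `+`)
  } else {
    s <- delta * W_gamma + b_gamma
  }
  exp(-pmax(0, s))
}

#' GRU-D input imputation
#'
#' `x_hat = m * x + (1 - m) * (gamma * x_last + (1 - gamma) * x_mean)`:
#' observed inputs pass through unchanged; missing inputs are a
#' decay-weighted blend of the last observed value and the feature's
#' empirical mean.
#'
#' @param x input values; `m` binary mask (1 = observed); `x_last` last
#'   observed value; `x_mean` empirical mean; `gamma` decay weight. All
#'   conformable.
#' @param m,x_last,x_mean,gamma see above.
#' @return imputed inputs, same shape as `x`.
#' @export
impute_input <- function(x, m, x_last, x_mean, gamma) {
  m * x + (1 - m) * (gamma * x_last + (1 - gamma) * x_mean)
}

#' Squared-error reconstruction loss
#'
#' Sum over samples, time steps and channels of the squared difference
#' between the post-imputation inputs (targets) and the reconstruction.
#'
#' @param x_bar reconstructed values (array or matrix).
#' @param x_hat post-imputation inputs of the same shape.
#' @return scalar loss.
#' @export
reconstruction_loss <- function(x_bar, x_hat) {
  if (!identical(dim(x_bar), dim(x_hat)))
    stop("reconstruction_loss: shape mismatch")
  sum((x_hat - x_bar)^2)
}

unif_mat <- function(nr, nc, s) matrix(stats::runif(nr * nc, -s, s), nr, nc)

#' Initialize GRU-D autoencoder parameters
#'
#' Input-decay weights are constrained diagonal (one independent decay per
#' feature); the optional hidden-state decay uses a full D x H map. Weights
#' are drawn uniformly in `[-1/sqrt(H), 1/sqrt(H)]`.
#'
#' @param D number of input channels.
#' @param H bottleneck (hidden) size.
#' @param hidden_decay include hidden-state decay (default TRUE).
#' @param seed integer seed.
#' @return parameter list of class `grud_params`.
#' @export
init_grud <- function(D, H, hidden_decay = TRUE, seed = 1L) {
  if (H < 1L) stop("init_grud: bottleneck size must be >= 1")
  with_seed(seed, {
    s <- 1 / sqrt(H)
    p <- list(
      w_gx = stats::runif(D, 0, 0.1), b_gx = numeric(D),
      W_xz = unif_mat(D, H, s), W_mz = unif_mat(D, H, s),
      W_xr = unif_mat(D, H, s), W_mr = unif_mat(D, H, s),
      W_xc = unif_mat(D, H, s), W_mc = unif_mat(D, H, s),
      U_z = unif_mat(H, H, s), U_r = unif_mat(H, H, s), U_c = unif_mat(H, H, s),
      b_z = numeric(H), b_r = numeric(H), b_c = numeric(H),
      V_z = unif_mat(H, H, s), V_r = unif_mat(H, H, s), V_c = unif_mat(H, H, s),
      c_z = numeric(H), c_r = numeric(H), c_c = numeric(H),
      W_out = unif_mat(H, D, s), b_out = numeric(D))
    if (hidden_decay) {
      p$W_hg <- unif_mat(D, H, 0.05)
      p$b_hg <- numeric(H)
    }
    structure(p, class = "grud_params", D = D, H = H,
              hidden_decay = hidden_decay)
  })
}

as_batch <- function(A, t, n, D) {
  # robust [N, T, D] -> N x D slice even when N == 1 or D == 1
  matrix(A[, t, ], n, D)
}

#' Encode temporal tensors with the GRU-D encoder
#'
#' Runs the 13 GRU-D steps with decay imputation feeding the gates and
#' returns the final hidden state `h_T` (the bottleneck embedding) for every
#' sample. Deterministic given parameters and input.
#'
#' @param tensors a [build_tensor_set()] result (arrays `X`, `M`, `Delta`,
#'   `Xlast` of dim `c(N, T, D)` and `x_mean` of length D).
#' @param params a [init_grud()] parameter list.
#' @param cache keep intermediate quantities for backpropagation (internal).
#' @return N x H embedding matrix, or (with `cache = TRUE`) a list with
#'   `h_T`, per-step caches and `x_hat` `[N, T, D]`.
#' @export
grud_encode <- function(tensors, params, cache = FALSE) {
  dims <- dim(tensors$X)
  n <- dims[1]; T_ <- dims[2]; D <- dims[3]
  H <- attr(params, "H")
  if (D != attr(params, "D"))
    stop("grud_encode: tensor has ", D, " channels but params expect ",
         attr(params, "D"))
  hidden_decay <- isTRUE(attr(params, "hidden_decay"))
  h <- matrix(0, n, H)
  steps <- if (cache) vector("list", T_)
  x_hat_all <- if (cache) array(0, dims)
  for (t in seq_len(T_)) {
    Xt <- as_batch(tensors$X, t, n, D); Mt <- as_batch(tensors$M, t, n, D)
    Dt <- as_batch(tensors$Delta, t, n, D)
    Lt <- as_batch(tensors$Xlast, t, n, D)
    gx <- decay_weight(Dt, params$w_gx, params$b_gx)
    xh <- impute_input(Xt, Mt, Lt,
                       matrix(tensors$x_mean, n, D, byrow = TRUE), gx)
    if (hidden_decay) {
      sh <- sweep(Dt %*% params$W_hg, 2L, params$b_hg, `+`)
      gh <- exp(-pmax(0, sh))
      hp <- gh * h
    } else {
      sh <- NULL; gh <- NULL; hp <- h
    }
    z <- sigmoid(sweep(xh %*% params$W_xz + Mt %*% params$W_mz +
                         hp %*% params$U_z, 2L, params$b_z, `+`))
    r <- sigmoid(sweep(xh %*% params$W_xr + Mt %*% params$W_mr +
                         hp %*% params$U_r, 2L, params$b_r, `+`))
    cc <- tanh(sweep(xh %*% params$W_xc + Mt %*% params$W_mc +
                       (r * hp) %*% params$U_c, 2L, params$b_c, `+`))
    h_new <- (1 - z) * hp + z * cc
    if (cache) {
      steps[[t]] <- list(Xt = Xt, Mt = Mt, Dt = Dt, Lt = Lt, gx = gx,
                         xh = xh, sh = sh, gh = gh, hprev = h, hp = hp,
                         z = z, r = r, cc = cc)
      x_hat_all[, t, ] <- xh
    }
    h <- h_new
  }
  if (cache) list(h_T = h, steps = steps, x_hat = x_hat_all) else h
}

#' Decode a bottleneck embedding into a reconstruction
#'
#' A plain gated recurrent decoder initialized with `h_T`, unrolled T steps
#' with zero inputs, with a linear readout per step.
#'
#' @param h_T N x H embedding matrix (or length-H vector).
#' @param params a [init_grud()] parameter list.
#' @param T_ number of steps to unroll (default 13).
#' @param cache keep intermediates for backpropagation (internal).
#' @return `[N, T, D]` reconstruction array (with `cache = TRUE`, a list).
#' @export
grud_decode <- function(h_T, params, T_ = GRID_POINTS, cache = FALSE) {
  if (!is.matrix(h_T)) h_T <- matrix(h_T, 1L)
  n <- nrow(h_T); H <- attr(params, "H"); D <- attr(params, "D")
  d <- h_T
  x_bar <- array(0, c(n, T_, D))
  steps <- if (cache) vector("list", T_)
  for (t in seq_len(T_)) {
    zd <- sigmoid(sweep(d %*% params$V_z, 2L, params$c_z, `+`))
    rd <- sigmoid(sweep(d %*% params$V_r, 2L, params$c_r, `+`))
    cd <- tanh(sweep((rd * d) %*% params$V_c, 2L, params$c_c, `+`))
    d_new <- (1 - zd) * d + zd * cd
    x_bar[, t, ] <- sweep(d_new %*% params$W_out, 2L, params$b_out, `+`)
    if (cache) steps[[t]] <- list(dprev = d, zd = zd, rd = rd, cd = cd,
                                  d = d_new)
    d <- d_new
  }
  if (cache) list(x_bar = x_bar, steps = steps) else x_bar
}

zero_like <- function(params) {
  g <- lapply(params, function(p) if (is.matrix(p)) 0 * p else numeric(length(p)))
  attributes(g) <- attributes(params)
  g
}

# Forward + analytic backward pass over one batch. Returns loss, gradients,
# and x_hat. Targets are the post-imputation inputs; when detach_targets is
# FALSE the target side of the loss also backpropagates into the input-decay
# parameters.
grud_backward <- function(tensors, params, detach_targets = TRUE) {
  enc <- grud_encode(tensors, params, cache = TRUE)
  T_ <- dim(tensors$X)[2]
  dec <- grud_decode(enc$h_T, params, T_ = T_, cache = TRUE)
  n <- dim(tensors$X)[1]; D <- attr(params, "D"); H <- attr(params, "H")
  hidden_decay <- isTRUE(attr(params, "hidden_decay"))
  E <- enc$x_hat - dec$x_bar              # [N, T, D]
  loss <- sum(E^2)
  g <- zero_like(params)
  # ---- decoder backward ----
  dd <- matrix(0, n, H)                   # grad wrt d_t
  for (t in T_:1) {
    st <- dec$steps[[t]]
    dxb <- -2 * matrix(E[, t, ], n, D)    # dL/dx_bar_t
    g$W_out <- g$W_out + crossprod(st$d, dxb)
    g$b_out <- g$b_out + colSums(dxb)
    dd <- dd + dxb %*% t(params$W_out)
    daz <- dd * (st$cd - st$dprev) * st$zd * (1 - st$zd)
    dac <- dd * st$zd * (1 - st$cd^2)
    drh <- dac %*% t(params$V_c)          # grad wrt (rd * dprev)
    dar <- drh * st$dprev * st$rd * (1 - st$rd)
    g$V_z <- g$V_z + crossprod(st$dprev, daz)
    g$V_r <- g$V_r + crossprod(st$dprev, dar)
    g$V_c <- g$V_c + crossprod(st$rd * st$dprev, dac)
    g$c_z <- g$c_z + colSums(daz)
    g$c_r <- g$c_r + colSums(dar)
    g$c_c <- g$c_c + colSums(dac)
    dd <- dd * (1 - st$zd) + daz %*% t(params$V_z) + dar %*% t(params$V_r) +
      drh * st$rd
  }
  dh <- dd                                # grad wrt encoder h_T
  # ---- encoder backward ----
  xmean <- matrix(tensors$x_mean, n, D, byrow = TRUE)
  for (t in T_:1) {
    st <- enc$steps[[t]]
    dz <- dh * (st$cc - st$hp)
    daz <- dz * st$z * (1 - st$z)
    dac <- dh * st$z * (1 - st$cc^2)
    drh <- dac %*% t(params$U_c)          # grad wrt (r * hp)
    dar <- drh * st$hp * st$r * (1 - st$r)
    dhp <- dh * (1 - st$z) + daz %*% t(params$U_z) + dar %*% t(params$U_r) +
      drh * st$r
    dxh <- daz %*% t(params$W_xz) + dar %*% t(params$W_xr) +
      dac %*% t(params$W_xc)
    if (!detach_targets) dxh <- dxh + 2 * matrix(E[, t, ], n, D)
    g$W_xz <- g$W_xz + crossprod(st$xh, daz)
    g$W_mz <- g$W_mz + crossprod(st$Mt, daz)
    g$W_xr <- g$W_xr + crossprod(st$xh, dar)
    g$W_mr <- g$W_mr + crossprod(st$Mt, dar)
    g$W_xc <- g$W_xc + crossprod(st$xh, dac)
    g$W_mc <- g$W_mc + crossprod(st$Mt, dac)
    g$U_z <- g$U_z + crossprod(st$hp, daz)
    g$U_r <- g$U_r + crossprod(st$hp, dar)
    g$U_c <- g$U_c + crossprod(st$r * st$hp, dac)
    g$b_z <- g$b_z + colSums(daz)
    g$b_r <- g$b_r + colSums(dar)
    g$b_c <- g$b_c + colSums(dac)
    if (hidden_decay) {
      dgh <- dhp * st$hprev
      dsh <- -dgh * st$gh * (st$sh > 0)
      g$W_hg <- g$W_hg + crossprod(st$Dt, dsh)
      g$b_hg <- g$b_hg + colSums(dsh)
      dh <- dhp * st$gh
    } else {
      dh <- dhp
    }
    # input-decay path: x_hat = m x + (1-m)(gx * x_last + (1-gx) * x_mean)
    dgx <- dxh * (1 - st$Mt) * (st$Lt - xmean)
    sx <- sweep(st$Dt, 2L, params$w_gx, `*`)
    sx <- sweep(sx, 2L, params$b_gx, `+`)
    dsx <- -dgx * st$gx * (sx > 0)
    g$w_gx <- g$w_gx + colSums(dsx * st$Dt)
    g$b_gx <- g$b_gx + colSums(dsx)
  }
  list(loss = loss, grads = g, x_hat = enc$x_hat, x_bar = dec$x_bar)
}

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

subset_tensors <- function(tensors, idx) {
  out <- tensors
  for (k in c("X", "M", "Delta", "Xlast"))
    out[[k]] <- tensors[[k]][idx, , , drop = FALSE]
  out$period_id <- tensors$period_id[idx]
  out$person_id <- tensors$person_id[idx]
  out
}

#' Training configuration for the autoencoders
#'
#' @param n_folds number of cross-validation folds (default 5).
#' @param epochs training epochs per fold.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param bottleneck hidden/bottleneck size H (default 120, the size used
#'   for real cohorts; the package's synthetic benchmark uses 16).
#' @param seed integer seed governing fold split, initialization and batch
#'   order.
#' @param detach_targets treat the post-imputation targets as constants in
#'   the gradient (default TRUE; blocks the shortcut failure mode where the
#'   model bends the imputation toward its own reconstruction).
#' @param hidden_decay include GRU-D hidden-state decay (default TRUE).
#' @param fold_by `"patient"` (default; a patient's periods never straddle
#'   the train/test divide) or `"period"`.
#' @param patience early-stopping patience in epochs on the training-loss
#'   plateau (default 10; `Inf` disables).
#' @param verbose print per-epoch losses.
#' @return list of class `train_config`.
#' @export
train_config <- function(n_folds = 5L, epochs = 30L, lr = 1e-3,
                         batch_size = 64L, bottleneck = 120L, seed = 1L,
                         detach_targets = TRUE, hidden_decay = TRUE,
                         fold_by = c("patient", "period"),
                         patience = 10L, verbose = FALSE) {
  if (n_folds < 2L) stop("train_config: n_folds must be >= 2")
  if (epochs < 1L) stop("train_config: epochs must be >= 1")
  if (bottleneck < 1L) stop("train_config: bottleneck must be >= 1")
  structure(list(n_folds = as.integer(n_folds), epochs = as.integer(epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 bottleneck = as.integer(bottleneck), seed = as.integer(seed),
                 detach_targets = isTRUE(detach_targets),
                 hidden_decay = isTRUE(hidden_decay),
                 fold_by = match.arg(fold_by), patience = patience,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Assign cross-validation folds
#'
#' @param person_id per-period patient ids.
#' @param config a [train_config()].
#' @return integer fold id per period (1..n_folds). With patient-level
#'   grouping, all periods of a patient share a fold.
#' @export
assign_folds <- function(person_id, config) {
  n <- length(person_id)
  if (config$fold_by == "patient") {
    pats <- unique(person_id)
    if (length(pats) < config$n_folds)
      stop("assign_folds: fewer patients (", length(pats),
           ") than folds (", config$n_folds, ")")
    pf <- with_seed(config$seed + 1000L,
      sample(rep_len(seq_len(config$n_folds), length(pats))))
    pf[match(person_id, pats)]
  } else {
    if (n < config$n_folds) stop("assign_folds: fewer periods than folds")
    with_seed(config$seed + 1000L,
      sample(rep_len(seq_len(config$n_folds), n)))
  }
}

train_one_grud <- function(train_tensors, config, fold_seed) {
  n <- dim(train_tensors$X)[1]
  D <- dim(train_tensors$X)[3]
  params <- init_grud(D, config$bottleneck,
                      hidden_decay = config$hidden_decay, seed = fold_seed)
  state <- adam_init(params)
  losses <- numeric(0)
  best <- Inf; stall <- 0L
  with_seed(fold_seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      ep_loss <- 0
      for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        bw <- grud_backward(subset_tensors(train_tensors, b), params,
                            detach_targets = config$detach_targets)
        ep_loss <- ep_loss + bw$loss
        st <- adam_step(params, bw$grads, state, lr = config$lr)
        params <- st$params; state <- st$state
      }
      losses <- c(losses, ep_loss)
      if (config$verbose) message("epoch ", ep, " loss ", signif(ep_loss, 6))
      if (ep_loss < best * (1 - 1e-8)) { best <- ep_loss; stall <- 0L }
      else stall <- stall + 1L
      if (stall >= config$patience) break
    }
  })
  list(params = params, losses = losses)
}

#' Train the GRU-D autoencoder with cross-validation
#'
#' Partitions periods into folds (grouped by patient by default), trains one
#' model per fold on the other folds' periods, and emits bottleneck
#' embeddings for every period from every fold model, flagged train/test.
#'
#' @param tensors a [build_tensor_set()] result.
#' @param config a [train_config()].
#' @return list of class `grud_fit`: `fold` (per-period fold id), `models`
#'   (per-fold parameter lists), `losses` (per-fold per-epoch training
#'   loss), `embeddings` (data.frame `period_id`, `fold_model`, `split`,
#'   `h_1..h_H`).
#' @export
train_grud_ae <- function(tensors, config = train_config()) {
  n <- dim(tensors$X)[1]
  if (n < config$n_folds) stop("train_grud_ae: fewer periods than folds")
  fold <- assign_folds(tensors$person_id, config)
  models <- vector("list", config$n_folds)
  losses <- vector("list", config$n_folds)
  embs <- vector("list", config$n_folds)
  for (k in seq_len(config$n_folds)) {
    tr <- which(fold != k)
    fitk <- train_one_grud(subset_tensors(tensors, tr), config,
                           fold_seed = config$seed + 17L * k)
    models[[k]] <- fitk$params
    losses[[k]] <- fitk$losses
    h <- grud_encode(tensors, fitk$params)
    colnames(h) <- paste0("h_", seq_len(ncol(h)))
    embs[[k]] <- data.frame(period_id = tensors$period_id, fold_model = k,
                            split = ifelse(fold == k, "test", "train"), h)
  }
  structure(list(fold = fold, models = models, losses = losses,
                 embeddings = do.call(rbind, embs), config = config),
            class = "grud_fit")
}

embedding_matrix <- function(fit, fold_model = 1L) {
  e <- fit$embeddings[fit$embeddings$fold_model == fold_model, , drop = FALSE]
  as.matrix(e[, grep("^h_", names(e)), drop = FALSE])
}

# ---- static sparse autoencoder baseline ----

init_sae <- function(D, H, seed = 1L) {
  with_seed(seed, {
    s <- 1 / sqrt(max(D, H))
    structure(list(W1 = unif_mat(D, H, s), b1 = numeric(H),
                   W2 = unif_mat(H, D, s), b2 = numeric(D)),
              class = "sae_params", D = D, H = H)
  })
}

sae_forward <- function(V, params) {
  e <- tanh(sweep(V %*% params$W1, 2L, params$b1, `+`))
  xb <- sweep(e %*% params$W2, 2L, params$b2, `+`)
  list(e = e, x_bar = xb)
}

sae_backward <- function(V, K, params) {
  Vin <- K * V                    # never-observed features enter as 0
  fw <- sae_forward(Vin, params)
  E <- K * (V - fw$x_bar)         # masked residual: masked cells contribute 0
  loss <- sum(E^2)
  dxb <- -2 * E
  g <- zero_like(params)
  g$W2 <- crossprod(fw$e, dxb)
  g$b2 <- colSums(dxb)
  de <- dxb %*% t(params$W2)
  da <- de * (1 - fw$e^2)
  g$W1 <- crossprod(Vin, da)
  g$b1 <- colSums(da)
  list(loss = loss, grads = g, x_bar = fw$x_bar)
}

#' Train the static sparse-autoencoder baseline
#'
#' Dense autoencoder on the static-transformed vectors (last observation in
#' the window); squared-error loss summed only over observed (mask = 1)
#' cells, so never-observed features are excluded from the loss. Fold
#' assignments are shared with the temporal model when `fold` is supplied.
#'
#' @param static_set a [build_static_set()] result.
#' @param config a [train_config()].
#' @param fold optional per-period fold assignment (reuse the temporal
#'   model's); computed from `config` otherwise.
#' @return list of class `sae_fit`, same layout as [train_grud_ae()].
#' @export
train_sae <- function(static_set, config = train_config(), fold = NULL) {
  V <- static_set$values; K <- static_set$mask
  n <- nrow(V)
  all_masked <- rowSums(K) == 0
  if (any(all_masked))
    warning("train_sae: ", sum(all_masked),
            " fully-masked sample(s) excluded from training")
  if (is.null(fold)) fold <- assign_folds(static_set$person_id, config)
  models <- vector("list", config$n_folds)
  losses <- vector("list", config$n_folds)
  embs <- vector("list", config$n_folds)
  for (k in seq_len(config$n_folds)) {
    tr <- which(fold != k & !all_masked)
    params <- init_sae(ncol(V), config$bottleneck,
                       seed = config$seed + 29L * k)
    state <- adam_init(params)
    fl <- numeric(0); best <- Inf; stall <- 0L
    with_seed(config$seed + 29L * k + 1L, {
      for (ep in seq_len(config$epochs)) {
        ord <- sample(tr)
        ep_loss <- 0
        for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
          bw <- sae_backward(V[b, , drop = FALSE], K[b, , drop = FALSE], params)
          ep_loss <- ep_loss + bw$loss
          st <- adam_step(params, bw$grads, state, lr = config$lr)
          params <- st$params; state <- st$state
        }
        fl <- c(fl, ep_loss)
        if (ep_loss < best * (1 - 1e-8)) { best <- ep_loss; stall <- 0L }
        else stall <- stall + 1L
        if (stall >= config$patience) break
      }
    })
    models[[k]] <- params
    losses[[k]] <- fl
    h <- sae_forward(K * V, params)$e
    colnames(h) <- paste0("h_", seq_len(ncol(h)))
    embs[[k]] <- data.frame(period_id = static_set$period_id, fold_model = k,
                            split = ifelse(fold == k, "test", "train"), h)
  }
  structure(list(fold = fold, models = models, losses = losses,
                 embeddings = do.call(rbind, embs), config = config),
            class = "sae_fit")
}
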