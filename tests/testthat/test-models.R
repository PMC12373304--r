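test_that("decay weight follows exp(-max(0, W delta + b)) exactly", {
  expect_equal(decay_weight(0, 0.5, 0), 1)
  expect_equal(decay_weight(10, -0.3, -2), 1)           # clamped at 0
  expect_equal(decay_weight(30, 0.1, 0), exp(-3))
  expect_equal(decay_weight(30, 0.1, 0), 0.049787, tolerance = 1e-5)
  expect_error(decay_weight(-1, 0.1), "non-negative")
  # matrix form with per-feature weights
  D <- matrix(c(0, 1, 2, 3), 2, 2)
  g <- decay_weight(D, c(1, 2), c(0, 0.5))
  expect_equal(g, exp(-pmax(0, sweep(D, 2, c(1, 2), `*`) +
                                 matrix(c(0, 0, 0.5, 0.5), 2, 2))))
})

test_that("input imputation blends last value and mean by the decay weight", {
  expect_equal(impute_input(2, 1, 99, -99, 0.123), 2)   # observed passthrough
  expect_equal(impute_input(0, 0, 1.5, 0, 1), 1.5)      # pure carry-forward
  expect_equal(impute_input(0, 0, 1, 0, exp(-3)), 0.049787, tolerance = 1e-5)
  expect_equal(impute_input(0, 0, 123, 0.7, 0), 0.7)    # decay-to-mean limit
})

test_that("decay and imputation match scalar brute force on random tuples", {
  set.seed(1)
  n <- 10000
  delta <- runif(n, 0, 20); w <- runif(n, -1, 1); b <- runif(n, -1, 1)
  g_vec <- decay_weight(delta, 1, 0)  # placeholder to keep vector API hot
  for (i in sample(n, 200)) {         # spot-check elementwise semantics
    expect_equal(decay_weight(delta[i], w[i], b[i]),
                 exp(-max(0, w[i] * delta[i] + b[i])), tolerance = 1e-12)
  }
  # full-vector check against the scalar loop
  gv <- decay_weight(delta, 0.37, -0.11)
  gs <- vapply(delta, function(d) exp(-max(0, 0.37 * d - 0.11)), 0)
  expect_equal(gv, gs, tolerance = 1e-12)
  x <- rnorm(n); m <- rbinom(n, 1, 0.5); xl <- rnorm(n); xm <- rnorm(n)
  gam <- runif(n)
  xi <- impute_input(x, m, xl, xm, gam)
  xs <- vapply(seq_len(n), function(i)
    if (m[i] == 1) x[i] else gam[i] * xl[i] + (1 - gam[i]) * xm[i], 0)
  expect_equal(xi, xs, tolerance = 1e-12)
  expect_true(all(xi[m == 1] == x[m == 1]))              # exact passthrough
  g0 <- decay_weight(runif(500, 0, 50), runif(500, 0, 2), runif(500, -1, 1))
  expect_true(all(g0 > 0 & g0 <= 1))
  # gamma non-increasing in delta for non-negative weights
  dd <- sort(runif(100, 0, 30))
  expect_true(all(diff(decay_weight(dd, 0.2, 0.1)) <= 0))
})

test_that("vectorized reconstruction loss equals the triple-loop sum", {
  set.seed(2)
  for (rep in 1:5) {
    xb <- array(rnorm(4 * 13 * 6), c(4, 13, 6))
    xh <- array(rnorm(4 * 13 * 6), c(4, 13, 6))
    loop <- 0
    for (i in 1:4) for (t in 1:13) for (d in 1:6)
      loop <- loop + (xh[i, t, d] - xb[i, t, d])^2
    expect_equal(reconstruction_loss(xb, xh), loop, tolerance = 1e-8)
  }
  x <- array(0, c(1, 2, 2))
  expect_equal(reconstruction_loss(x, x), 0)
  x2 <- x; x2[1, 1, 1] <- 2
  expect_equal(reconstruction_loss(x, x2), 4)
  expect_error(reconstruction_loss(x, array(0, c(2, 2, 2))), "shape")
})

test_that("analytic gradients match numerical differentiation", {
  ts <- random_tensor_set(3, 4, 3, x_mean = rep(0.3, 3), seed = 5)
  for (hd in c(TRUE, FALSE)) {
    params <- init_grud(3, 4, hidden_decay = hd, seed = 7)
    bw <- aompheno:::grud_backward(ts, params, detach_targets = FALSE)
    f <- function(p) {
      enc <- grud_encode(ts, p, cache = TRUE)
      reconstruction_loss(grud_decode(enc$h_T, p, T_ = 4), enc$x_hat)
    }
    for (k in c("w_gx", "W_xz", "U_c", "V_r", "W_out", "b_c",
                if (hd) "W_hg")) {
      pk <- params[[k]]
      idx <- sample(length(pk), min(4, length(pk)))
      for (j in idx) {
        eps <- 1e-5
        p1 <- params; p1[[k]][j] <- pk[j] + eps
        p2 <- params; p2[[k]][j] <- pk[j] - eps
        num <- (f(p1) - f(p2)) / (2 * eps)
        expect_equal(bw$grads[[k]][j], num, tolerance = 1e-5)
      }
    }
  }
})

test_that("encoder is deterministic and respects imputation identities", {
  ts <- random_tensor_set(5, 13, 6, seed = 11)
  params <- init_grud(6, 8, seed = 3)
  h1 <- grud_encode(ts, params)
  h2 <- grud_encode(ts, params)
  expect_identical(h1, h2)
  expect_equal(dim(h1), c(5L, 8L))
  # duplicated period gives an identical embedding
  ts2 <- aompheno:::subset_tensors(ts, c(1, 1, 2))
  h3 <- grud_encode(ts2, params)
  expect_equal(h3[1, ], h3[2, ])
  # fully-observed tensor: x_hat reduces to x exactly
  tsf <- random_tensor_set(3, 13, 6, presence = 1, seed = 12)
  enc <- grud_encode(tsf, params, cache = TRUE)
  expect_equal(enc$x_hat, tsf$X)
  # dimension mismatch names the channel count
  expect_error(grud_encode(random_tensor_set(2, 13, 4, seed = 1), params),
               "4 channels")
})

test_that("feature permutation symmetry holds on a 3-feature toy", {
  ts <- random_tensor_set(4, 6, 3, x_mean = c(0.1, -0.2, 0.5), seed = 21)
  params <- init_grud(3, 5, seed = 9)
  perm <- c(3, 1, 2)
  tsp <- ts
  for (k in c("X", "M", "Delta", "Xlast")) tsp[[k]] <- ts[[k]][, , perm]
  tsp$x_mean <- ts$x_mean[perm]
  pp <- params
  for (k in c("w_gx", "b_gx")) pp[[k]] <- params[[k]][perm]
  for (k in c("W_xz", "W_mz", "W_xr", "W_mr", "W_xc", "W_mc", "W_hg"))
    pp[[k]] <- params[[k]][perm, , drop = FALSE]
  expect_equal(grud_encode(tsp, pp), grud_encode(ts, params),
               tolerance = 1e-12)
})

test_that("decoder has the contracted shape and degenerate behavior", {
  params <- init_grud(4, 6, seed = 2)
  h <- matrix(rnorm(3 * 6), 3, 6)
  xb <- grud_decode(h, params, T_ = 13)
  expect_equal(dim(xb), c(3L, 13L, 4L))
  # zero weights: reconstruction is the readout bias at every step
  pz <- params
  for (k in names(pz)) pz[[k]] <- pz[[k]] * 0
  pz$b_out <- c(1, 2, 3, 4)
  xz <- grud_decode(h, pz, T_ = 5)
  for (t in 1:5) expect_equal(xz[2, t, ], c(1, 2, 3, 4))
})

test_that("training reduces loss, is seed-reproducible, and guards folds", {
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(n_folds = 1), "n_folds")
  ts <- random_tensor_set(40, 13, 5, seed = 31)
  ts$person_id <- rep(1:20, each = 2)
  cfg <- train_config(n_folds = 4, epochs = 8, bottleneck = 4,
                      batch_size = 16, seed = 3)
  fit <- train_grud_ae(ts, cfg)
  for (k in 1:4) {
    expect_lt(tail(fit$losses[[k]], 1), fit$losses[[k]][1])
  }
  # same seed, same final loss
  fit2 <- train_grud_ae(ts, cfg)
  expect_equal(fit$losses, fit2$losses)
  # patient-grouped folds never straddle the divide
  expect_true(all(tapply(fit$fold, ts$person_id,
                         function(f) length(unique(f))) == 1))
  expect_error(train_grud_ae(aompheno:::subset_tensors(ts, 1:3),
                             train_config(n_folds = 5, epochs = 1)),
               "fewer")
  emb <- fit$embeddings
  expect_setequal(unique(emb$split), c("train", "test"))
  expect_equal(nrow(emb), 40 * 4)
})

test_that("trained autoencoder recovers a low-rank signal", {
  # rank-1 temporal data with smooth sinusoidal loadings (clinical
  # trajectories vary smoothly over months), fully observed: the trained
  # reconstruction should correlate strongly with the inputs
  set.seed(41)
  n <- 60; T_ <- 13; D <- 5
  u <- rnorm(n)
  tg <- seq_len(T_)
  v <- sapply(1:D, function(d)
    sin(2 * pi * tg / T_ * sample(1:2, 1) + runif(1, 0, 2 * pi)))
  X <- array(0, c(n, T_, D))
  for (i in 1:n) X[i, , ] <- u[i] * v
  ts <- list(X = X, M = array(1, c(n, T_, D)), Delta = array(0, c(n, T_, D)),
             Xlast = array(0, c(n, T_, D)), x_mean = rep(0, D),
             period_id = 1:n, person_id = 1:n)
  cfg <- train_config(n_folds = 2, epochs = 300, lr = 1e-2, bottleneck = 8,
                      batch_size = 60, seed = 5, patience = Inf)
  fit <- train_grud_ae(ts, cfg)
  enc <- grud_encode(ts, fit$models[[1]], cache = TRUE)
  xb <- grud_decode(enc$h_T, fit$models[[1]], T_ = T_)
  expect_gte(cor(as.vector(xb), as.vector(enc$x_hat)), 0.9)
})

test_that("static autoencoder masks unobserved cells out of loss and gradient", {
  set.seed(51)
  V <- matrix(rnorm(20 * 6), 20, 6)
  K <- matrix(rbinom(20 * 6, 1, 0.7), 20, 6)
  params <- aompheno:::init_sae(6, 3, seed = 1)
  bw <- aompheno:::sae_backward(V, K, params)
  # fully masked sample contributes zero loss
  K0 <- K; K0[1, ] <- 0
  bw0 <- aompheno:::sae_backward(V[1, , drop = FALSE],
                                 K0[1, , drop = FALSE], params)
  expect_equal(bw0$loss, 0)
  # changing a masked cell's value changes nothing
  V2 <- V; V2[which(K == 0)[1]] <- 999
  bw2 <- aompheno:::sae_backward(V2, K, params)
  expect_equal(bw$loss, bw2$loss)
  # gradient check on the masked loss (masked inputs enter the encoder as 0)
  f <- function(p) {
    xb <- aompheno:::sae_forward(K * V, p)$x_bar
    sum((K * (V - xb))^2)
  }
  for (k in names(params)) {
    j <- 1
    eps <- 1e-6
    p1 <- params; p1[[k]][j] <- p1[[k]][j] + eps
    p2 <- params; p2[[k]][j] <- p2[[k]][j] - eps
    expect_equal(bw$grads[[k]][j], (f(p1) - f(p2)) / (2 * eps),
                 tolerance = 1e-4)
  }
  # rank-1 static data: observed-cell MSE well below data variance
  u <- rnorm(40); w <- rnorm(6)
  Vr <- outer(u, w); Kr <- matrix(1, 40, 6)
  sset <- list(values = Vr, mask = Kr, period_id = 1:40, person_id = 1:40)
  sfit <- train_sae(sset, train_config(n_folds = 2, epochs = 80,
                                       bottleneck = 2, batch_size = 16,
                                       seed = 7, patience = Inf))
  xb <- aompheno:::sae_forward(Vr, sfit$models[[1]])$x_bar
  expect_lt(mean((Vr - xb)^2), stats::var(as.vector(Vr)))
})
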