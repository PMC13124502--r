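# PCA at the 90% criterion, the LSTM classifier (forward pass, gradients,
# training) and the classical baselines.

test_that("PCA matches an independent decomposition and the 90% rule", {
  set.seed(1)
  X <- matrix(rnorm(50 * 11), 50, 11)
  m <- fit_pca(X)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(m$eigenvalues, unname(pr$sdev^2), tolerance = 1e-8)
  # trace identity: eigenvalue sum = total variance
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)
  # orthonormal loadings
  expect_lt(max(abs(crossprod(m$W_k) - diag(m$k))), 1e-8)
  # columns agree with prcomp up to sign
  for (j in seq_len(m$k)) {
    expect_equal(min(sum(abs(m$W[, j] - pr$rotation[, j])),
                     sum(abs(m$W[, j] + pr$rotation[, j]))), 0,
                 tolerance = 1e-6)
  }
  # k is minimal for the criterion
  expect_gte(m$cumvar[m$k], 0.90)
  if (m$k > 1) expect_lt(m$cumvar[m$k - 1], 0.90)
  # sign convention: largest-magnitude entry positive
  for (j in seq_len(ncol(m$W))) {
    expect_gt(m$W[which.max(abs(m$W[, j])), j], 0)
  }
})

test_that("PCA handles degenerate spectra as the rule dictates", {
  set.seed(2)
  # rank 1: points on a line in 5-D
  d <- rnorm(5)
  X <- outer(rnorm(40), d)
  m <- fit_pca(X)
  expect_equal(m$k, 1)
  expect_equal(m$cumvar_k, 1.0, tolerance = 1e-12)

  # exactly isotropic sample covariance in 11-D: k forced to 10
  raw <- matrix(rnorm(40 * 11), 40, 11)
  Q <- qr.Q(qr(sweep(raw, 2, colMeans(raw))))[, 1:11]
  Xi <- Q * sqrt(39)
  mi <- fit_pca(Xi)
  expect_equal(mi$k, 10)
})

test_that("PCA projection behaves linearly and reconstructs rank-k data", {
  set.seed(3)
  X <- matrix(rnorm(30 * 6), 30, 6)
  m <- fit_pca(X)
  mu <- matrix(m$means, 3, 6, byrow = TRUE)
  expect_lt(max(abs(transform_pca(m, mu))), 1e-10)
  # batch consistency
  Z <- transform_pca(m, X)
  expect_equal(Z[7, ], drop(transform_pca(m, X[7, ])), tolerance = 1e-12)
  # projector identity on rank-k data
  B <- matrix(rnorm(4 * 6), 4, 6)
  Xr <- matrix(rnorm(40 * 4), 40, 4) %*% B
  mr <- fit_pca(Xr, var_threshold = 0.999999)
  Zr <- transform_pca(mr, Xr)
  back <- Zr %*% t(mr$W_k) + matrix(mr$means, 40, 6, byrow = TRUE)
  expect_lt(max(abs(back - Xr)), 1e-8)
})

test_that("the LSTM gate recurrence follows the printed equations", {
  cfg <- train_config(hidden = 1, fc = c(2, 2, 2), dropout = c(0, 0, 0),
                      seed = 1)
  w <- init_lstm_weights(1, cfg)
  w$Wg <- matrix(1, 2, 4)
  w$bg <- rep(0, 4)
  out <- lstm_forward(matrix(1, 1, 1), w)
  s1 <- 1 / (1 + exp(-1))
  c1 <- s1 * tanh(1)
  h1 <- s1 * tanh(c1)
  expect_equal(unname(out$h_T), h1, tolerance = 1e-12)
  expect_equal(round(c1, 4), 0.5568)
  expect_equal(round(h1, 4), 0.3696)

  # all-zero weights force h = 0 at every step
  w0 <- init_lstm_weights(3, train_config(hidden = 4, fc = c(3, 3, 3)))
  for (p in PARAM_NAMES) w0[[p]] <- w0[[p]] * 0
  rec <- lstm_recurrence(array(rnorm(2 * 5 * 3), c(2, 5, 3)), w0)
  expect_equal(max(abs(rec$h)), 0)
})

test_that("vectorized LSTM equals the naive per-equation reference", {
  for (s in 1:5) {
    set.seed(s)
    cfg <- train_config(hidden = 3, fc = c(6, 5, 4), seed = s)
    w <- init_lstm_weights(2, cfg)
    X <- matrix(rnorm(4 * 2), 4, 2)
    got <- lstm_forward(X, w)
    want <- lstm_naive_forward(X, w)
    expect_lt(max(abs(got$h_T - want$h_T)), 1e-10)
    expect_lt(max(abs(got$probs - want$probs)), 1e-10)
    expect_true(all(abs(got$h_T) < 1))
    expect_equal(sum(got$probs), 1, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  cfg <- train_config(hidden = 4, fc = c(6, 5, 4), dropout = c(0, 0, 0))
  w <- init_lstm_weights(3, cfg)
  X <- array(rnorm(6 * 3 * 3), c(6, 3, 3))
  Y <- diag(3)[sample(1:3, 6, replace = TRUE), ]
  bw <- lstm_backward(X, Y, w)
  eps <- 1e-6
  for (p in PARAM_NAMES) {
    idx <- sample(length(w[[p]]), min(4, length(w[[p]])))
    for (i in idx) {
      wp <- w; wp[[p]][i] <- wp[[p]][i] + eps
      wm <- w; wm[[p]][i] <- wm[[p]][i] - eps
      num <- (lstm_backward(X, Y, wp)$loss - lstm_backward(X, Y, wm)$loss) /
        (2 * eps)
      expect_lt(abs(num - bw$grads[[p]][i]), 1e-5)
    }
  }
})

test_that("LSTM training is deterministic and learns separable data", {
  toy <- make_toy_tables(n_participants = 8, trials_per_class = 4,
                         effect = 2.5, seed = 21, n_features = 5)
  lab <- toy$trial_table$label
  arr <- array(0, c(nrow(toy$trial_table), 4, 5))
  for (i in seq_len(nrow(toy$trial_table))) {
    rows <- toy$window_table[toy$window_table$trial ==
                               toy$trial_table$trial[i], ]
    arr[i, , ] <- as.matrix(rows[order(rows$window_index),
                                 FEATURE_NAMES[1:5]])
  }
  set.seed(1)
  idx_val <- sample(dim(arr)[1], 20)
  cfg <- train_config(hidden = 16, fc = c(16, 8, 8),
                      max_epochs = 40, seed = 5)
  fit1 <- train_lstm(arr[-idx_val, , ], lab[-idx_val],
                     arr[idx_val, , ], lab[idx_val], cfg)
  fit2 <- train_lstm(arr[-idx_val, , ], lab[-idx_val],
                     arr[idx_val, , ], lab[idx_val], cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$weights, fit2$weights)
  expect_gt(max(fit1$history$val_acc), 0.8)
  # dropout off at inference: repeated evaluation identical
  p1 <- predict_lstm(fit1$weights, arr[idx_val, , ])
  p2 <- predict_lstm(fit1$weights, arr[idx_val, , ])
  expect_identical(p1, p2)
})

test_that("baselines solve separable problems and are deterministic", {
  set.seed(31)
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, 0), n, 3),
             matrix(rnorm(n * 3, 4), n, 3),
             matrix(rnorm(n * 3, -4), n, 3))
  y <- rep(c("positive", "neutral", "negative"), each = n)
  test_idx <- seq(1, 3 * n, by = 5)
  for (kind in c("svm", "rf", "knn", "xgb")) {
    m <- train_baseline(kind, X[-test_idx, ], y[-test_idx], seed = 7)
    pred <- predict_baseline(m, X[test_idx, ])
    expect_gte(mean(as.character(pred) == y[test_idx]), 0.95)
    m2 <- train_baseline(kind, X[-test_idx, ], y[-test_idx], seed = 7)
    expect_identical(as.character(predict_baseline(m2, X[test_idx, ])),
                     as.character(pred))
  }
  # single training class: predicts that class everywhere
  m1 <- train_baseline("rf", X[1:n, ], y[1:n], seed = 1)
  expect_true(all(as.character(predict_baseline(m1, X[test_idx, ])) ==
                    "positive"))
  expect_error(train_baseline("mlp", X, y))
})
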