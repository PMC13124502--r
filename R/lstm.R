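# LSTM classifier implemented from the gate equations:
#   f_t = sigmoid(W_f [h_{t-1}, x_t] + b_f)
#   i_t = sigmoid(W_i [h_{t-1}, x_t] + b_i)
#   cbar_t = tanh(W_c [h_{t-1}, x_t] + b_c)
#   c_t = f_t * c_{t-1} + i_t * cbar_t
#   o_t = sigmoid(W_o [h_{t-1}, x_t] + b_o)
#   h_t = o_t * tanh(c_t)
# followed by three fully connected layers (ReLU, inverted dropout) and a
# softmax output; trained with Adam, reduce-on-plateau learning rate and
# early stopping on validation loss. Pure matrix code; no external
# deep-learning dependency.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' LSTM training configuration
#'
#' @param hidden LSTM hidden units (default 96).
#' @param fc fully connected layer widths (default 128, 64, 32).
#' @param dropout dropout rates of the three FC hidden layers
#'   (default 0.4, 0.3, 0.2), active only during training.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @param max_epochs maximum training epochs (default 100).
#' @param lr_patience epochs without validation-loss improvement before the
#'   learning rate is halved (default 5).
#' @param lr_factor learning-rate reduction factor (default 0.5).
#' @param stop_patience epochs without improvement before early stopping;
#'   best-validation weights are restored (default 10).
#' @param seed RNG seed controlling weight initialization, dropout masks
#'   and batch order.
#' @return `train_config` list.
#' @export
train_config <- function(hidden = 96, fc = c(128, 64, 32),
                         dropout = c(0.4, 0.3, 0.2),
                         learning_rate = 0.001, batch_size = 32,
                         max_epochs = 100, lr_patience = 5, lr_factor = 0.5,
                         stop_patience = 10, seed = 1L) {
  stopifnot(hidden > 0, length(fc) == 3, length(dropout) == 3,
            learning_rate > 0, batch_size > 0, max_epochs > 0)
  structure(list(hidden = hidden, fc = fc, dropout = dropout,
                 learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs, lr_patience = lr_patience,
                 lr_factor = lr_factor, stop_patience = stop_patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Glorot-uniform matrix.
glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize LSTM + FC weights
#'
#' @param input_dim dimension of each time-step input.
#' @param cfg a [train_config()].
#' @param n_classes output classes (default 3).
#' @return `lstm_weights` list: `Wg` ((hidden+input) x 4*hidden, gate order
#'   f, i, c, o), `bg` (forget biases initialized at 1), FC weights
#'   `W1..W4`, biases `b1..b4`, and dims.
#' @export
init_lstm_weights <- function(input_dim, cfg = train_config(), n_classes = 3) {
  H <- cfg$hidden
  fc <- cfg$fc
  Wg <- glorot(H + input_dim, 4 * H)
  bg <- c(rep(1, H), rep(0, 3 * H))  # forget-gate bias 1
  w <- list(Wg = Wg, bg = bg,
            W1 = glorot(H, fc[1]), b1 = rep(0, fc[1]),
            W2 = glorot(fc[1], fc[2]), b2 = rep(0, fc[2]),
            W3 = glorot(fc[2], fc[3]), b3 = rep(0, fc[3]),
            W4 = glorot(fc[3], n_classes), b4 = rep(0, n_classes),
            hidden = H, input_dim = input_dim, n_classes = n_classes,
            dropout = cfg$dropout)
  class(w) <- "lstm_weights"
  w
}

# Batched LSTM recurrence. X: n x T x k array. Returns h_T (n x H) and,
# when cache = TRUE, all per-step quantities needed for BPTT.
lstm_recurrence <- function(X, w, h0 = NULL, c0 = NULL, cache = FALSE) {
  n <- dim(X)[1]; Tn <- dim(X)[2]
  H <- w$hidden
  h <- if (is.null(h0)) matrix(0, n, H) else h0
  cc <- if (is.null(c0)) matrix(0, n, H) else c0
  steps <- if (cache) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    inp <- cbind(h, matrix(X[, t, ], n))
    pre <- inp %*% w$Wg + matrix(w$bg, n, 4 * H, byrow = TRUE)
    f <- sigmoid(pre[, 1:H, drop = FALSE])
    i <- sigmoid(pre[, (H + 1):(2 * H), drop = FALSE])
    cb <- tanh(pre[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(pre[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * cb
    tc <- tanh(cc)
    h <- o * tc
    if (cache) steps[[t]] <- list(inp = inp, f = f, i = i, cb = cb, o = o,
                                  c = cc, c_prev = c_prev, tc = tc)
  }
  list(h = h, c = cc, steps = steps)
}

# FC head. Returns probabilities and (training mode) the cache for backprop.
fc_forward <- function(h, w, training = FALSE) {
  drop_mask <- function(a, rate) {
    if (!training || rate <= 0) return(NULL)
    matrix(stats::rbinom(length(a), 1, 1 - rate) / (1 - rate),
           nrow(a), ncol(a))
  }
  n <- nrow(h)
  z1 <- h %*% w$W1 + matrix(w$b1, n, length(w$b1), byrow = TRUE)
  a1 <- pmax(z1, 0); m1 <- drop_mask(a1, w$dropout[1])
  d1 <- if (is.null(m1)) a1 else a1 * m1
  z2 <- d1 %*% w$W2 + matrix(w$b2, n, length(w$b2), byrow = TRUE)
  a2 <- pmax(z2, 0); m2 <- drop_mask(a2, w$dropout[2])
  d2 <- if (is.null(m2)) a2 else a2 * m2
  z3 <- d2 %*% w$W3 + matrix(w$b3, n, length(w$b3), byrow = TRUE)
  a3 <- pmax(z3, 0); m3 <- drop_mask(a3, w$dropout[3])
  d3 <- if (is.null(m3)) a3 else a3 * m3
  logits <- d3 %*% w$W4 + matrix(w$b4, n, length(w$b4), byrow = TRUE)
  lmax <- apply(logits, 1, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  list(probs = probs, logits = logits,
       cache = list(z1 = z1, d1 = d1, m1 = m1, z2 = z2, d2 = d2, m2 = m2,
                    z3 = z3, d3 = d3, m3 = m3))
}

#' LSTM forward pass
#'
#' Runs the gate recurrence over one sequence (or a batch) and the fully
#' connected softmax head in inference mode (dropout off).
#'
#' @param sequence T x k matrix (one sequence) or n x T x k array (batch).
#' @param weights an [init_lstm_weights()] object.
#' @param h0,c0 optional initial hidden/cell state (default zero).
#' @return list: `h_T` (final hidden state), `probs` (class
#'   probabilities), `logits`.
#' @export
lstm_forward <- function(sequence, weights, h0 = NULL, c0 = NULL) {
  X <- if (length(dim(sequence)) == 2) {
    array(sequence, c(1, nrow(sequence), ncol(sequence)))
  } else sequence
  stopifnot(dim(X)[3] == weights$input_dim)
  rec <- lstm_recurrence(X, weights, h0, c0)
  fc <- fc_forward(rec$h, weights, training = FALSE)
  list(h_T = drop(rec$h), probs = drop(fc$probs), logits = drop(fc$logits))
}

# Full forward + backward pass on one minibatch; returns loss and gradients.
lstm_backward <- function(X, Y, w) {
  n <- dim(X)[1]; Tn <- dim(X)[2]; H <- w$hidden
  rec <- lstm_recurrence(X, w, cache = TRUE)
  fc <- fc_forward(rec$h, w, training = TRUE)
  eps <- 1e-12
  loss <- -mean(log(rowSums(fc$probs * Y) + eps))

  g <- list()
  cache <- fc$cache
  dlogits <- (fc$probs - Y) / n
  g$W4 <- crossprod(cache$d3, dlogits); g$b4 <- colSums(dlogits)
  dd3 <- tcrossprod(dlogits, w$W4)
  da3 <- if (is.null(cache$m3)) dd3 else dd3 * cache$m3
  dz3 <- da3 * (cache$z3 > 0)
  g$W3 <- crossprod(cache$d2, dz3); g$b3 <- colSums(dz3)
  dd2 <- tcrossprod(dz3, w$W3)
  da2 <- if (is.null(cache$m2)) dd2 else dd2 * cache$m2
  dz2 <- da2 * (cache$z2 > 0)
  g$W2 <- crossprod(cache$d1, dz2); g$b2 <- colSums(dz2)
  dd1 <- tcrossprod(dz2, w$W2)
  da1 <- if (is.null(cache$m1)) dd1 else dd1 * cache$m1
  dz1 <- da1 * (cache$z1 > 0)
  g$W1 <- crossprod(rec$h, dz1); g$b1 <- colSums(dz1)

  dh <- tcrossprod(dz1, w$W1)
  dc <- matrix(0, n, H)
  g$Wg <- matrix(0, nrow(w$Wg), ncol(w$Wg))
  g$bg <- numeric(length(w$bg))
  for (t in rev(seq_len(Tn))) {
    s <- rec$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    dcb <- dc * s$i
    di <- dc * s$cb
    df <- dc * s$c_prev
    dpre <- cbind(df * s$f * (1 - s$f),
                  di * s$i * (1 - s$i),
                  dcb * (1 - s$cb^2),
                  do * s$o * (1 - s$o))
    g$Wg <- g$Wg + crossprod(s$inp, dpre)
    g$bg <- g$bg + colSums(dpre)
    dinp <- tcrossprod(dpre, w$Wg)
    dh <- dinp[, 1:H, drop = FALSE]
    dc <- dc * s$f
  }
  list(loss = loss, grads = g)
}

PARAM_NAMES <- c("Wg", "bg", "W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")

# Mean cross-entropy and accuracy in inference mode.
lstm_evaluate <- function(X, y_int, w) {
  rec <- lstm_recurrence(X, w)
  fc <- fc_forward(rec$h, w, training = FALSE)
  n <- dim(X)[1]
  picked <- fc$probs[cbind(seq_len(n), y_int)]
  pred <- max.col(fc$probs, ties.method = "first")
  list(loss = -mean(log(picked + 1e-12)), acc = mean(pred == y_int),
       pred = pred, probs = fc$probs)
}

#' Train the LSTM classifier
#'
#' Minibatch Adam on the softmax cross-entropy, with reduce-on-plateau
#' learning-rate scheduling and early stopping on the validation loss
#' (best-validation weights restored). Deterministic given `cfg$seed`.
#'
#' @param X_train n x T x k array of training sequences.
#' @param y_train integer class labels in 1..n_classes (or a factor).
#' @param X_val,y_val validation sequences/labels for scheduling and early
#'   stopping.
#' @param cfg a [train_config()].
#' @return list: `weights` (trained, best-validation), `history`
#'   (data.frame: epoch, train_loss, val_loss, val_acc, lr), `best_epoch`.
#' @export
train_lstm <- function(X_train, y_train, X_val, y_val, cfg = train_config()) {
  y_train <- as.integer(as.factor(y_train))
  y_val <- as.integer(as.factor(y_val))
  n <- dim(X_train)[1]
  k <- dim(X_train)[3]
  n_classes <- max(c(y_train, y_val))
  if (length(unique(y_val)) < n_classes) {
    warning("validation set is missing a class")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  w <- init_lstm_weights(k, cfg, n_classes)
  Y <- matrix(0, n, n_classes)
  Y[cbind(seq_len(n), y_train)] <- 1

  adam_m <- lapply(w[PARAM_NAMES], function(p) p * 0)
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; epsa <- 1e-8
  lr <- cfg$learning_rate
  step <- 0
  best_loss <- Inf; best_w <- w; best_epoch <- 0
  since_best <- 0; since_lr <- 0
  hist <- list()
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    tl <- 0; nb <- 0
    for (s in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[s:min(s + cfg$batch_size - 1, n)]
      bw <- lstm_backward(X_train[idx, , , drop = FALSE],
                          Y[idx, , drop = FALSE], w)
      step <- step + 1
      for (p in PARAM_NAMES) {
        gp <- bw$grads[[p]]
        adam_m[[p]] <- b1 * adam_m[[p]] + (1 - b1) * gp
        adam_v[[p]] <- b2 * adam_v[[p]] + (1 - b2) * gp^2
        mhat <- adam_m[[p]] / (1 - b1^step)
        vhat <- adam_v[[p]] / (1 - b2^step)
        w[[p]] <- w[[p]] - lr * mhat / (sqrt(vhat) + epsa)
      }
      tl <- tl + bw$loss; nb <- nb + 1
    }
    ev <- lstm_evaluate(X_val, y_val, w)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tl / nb,
                                val_loss = ev$loss, val_acc = ev$acc, lr = lr)
    if (ev$loss < best_loss - 1e-6) {
      best_loss <- ev$loss; best_w <- w; best_epoch <- epoch
      since_best <- 0; since_lr <- 0
    } else {
      since_best <- since_best + 1
      since_lr <- since_lr + 1
      if (since_lr >= cfg$lr_patience) {
        lr <- lr * cfg$lr_factor
        since_lr <- 0
      }
      if (since_best >= cfg$stop_patience) break
    }
  }
  list(weights = best_w, history = do.call(rbind, hist),
       best_epoch = best_epoch)
}

#' Predict classes with a trained LSTM
#'
#' @param weights trained [init_lstm_weights()] object.
#' @param X n x T x k array.
#' @return list: `pred` (integer classes), `probs`.
#' @export
predict_lstm <- function(weights, X) {
  rec <- lstm_recurrence(X, weights)
  fc <- fc_forward(rec$h, weights, training = FALSE)
  list(pred = max.col(fc$probs, ties.method = "first"), probs = fc$probs)
}
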