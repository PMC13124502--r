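# Independent oracle implementations used to cross-check the package's
# numerical routines. Deliberately naive (loops, no shared code paths).

# Sample entropy by brute-force double loop over template pairs.
sampen_bruteforce <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  if (r == 0) r <- .Machine$double.eps
  count <- function(dim) {
    nt <- n - m
    cnt <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        d <- 0
        for (k in 0:(dim - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1
      }
    }
    cnt
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# LSTM forward pass evaluated unit by unit, equation by equation.
lstm_naive_forward <- function(X, w) {
  H <- w$hidden; k <- w$input_dim; Tn <- nrow(X)
  sig <- function(v) 1 / (1 + exp(-v))
  h <- rep(0, H); cc <- rep(0, H)
  Wf <- t(w$Wg[, 1:H]); Wi <- t(w$Wg[, (H + 1):(2 * H)])
  Wc <- t(w$Wg[, (2 * H + 1):(3 * H)]); Wo <- t(w$Wg[, (3 * H + 1):(4 * H)])
  bf <- w$bg[1:H]; bi <- w$bg[(H + 1):(2 * H)]
  bc <- w$bg[(2 * H + 1):(3 * H)]; bo <- w$bg[(3 * H + 1):(4 * H)]
  for (t in 1:Tn) {
    hx <- c(h, X[t, ])
    f <- i <- cb <- o <- numeric(H)
    for (u in 1:H) {
      f[u] <- sig(sum(Wf[u, ] * hx) + bf[u])
      i[u] <- sig(sum(Wi[u, ] * hx) + bi[u])
      cb[u] <- tanh(sum(Wc[u, ] * hx) + bc[u])
      o[u] <- sig(sum(Wo[u, ] * hx) + bo[u])
    }
    cc <- f * cc + i * cb
    h <- o * tanh(cc)
  }
  # FC head without dropout
  relu <- function(v) pmax(v, 0)
  a1 <- relu(as.numeric(h %*% w$W1) + w$b1)
  a2 <- relu(as.numeric(a1 %*% w$W2) + w$b2)
  a3 <- relu(as.numeric(a2 %*% w$W3) + w$b3)
  lg <- as.numeric(a3 %*% w$W4) + w$b4
  list(h_T = h, probs = exp(lg - max(lg)) / sum(exp(lg - max(lg))))
}

# Repeated-measures ANOVA via stats::aov with an Error() stratum, plus
# Greenhouse-Geisser epsilon from the eigenvalues of the double-centered
# condition covariance (an algebraically different route than the
# package's moment formula).
rm_anova_aov_oracle <- function(design) {
  n <- nrow(design); k <- ncol(design)
  df <- data.frame(y = as.vector(design),
                   subj = factor(rep(seq_len(n), k)),
                   cond = factor(rep(seq_len(k), each = n)))
  fit <- summary(aov(y ~ cond + Error(subj / cond), data = df))
  tab <- fit[["Error: subj:cond"]][[1]]
  S <- cov(design)
  Cm <- diag(k) - 1 / k
  lam <- eigen(Cm %*% S %*% Cm, symmetric = FALSE, only.values = TRUE)$values
  lam <- Re(lam[Re(lam) > 1e-12])
  eps <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  list(F = tab["cond", "F value"], p = tab["cond", "Pr(>F)"],
       epsilon = eps)
}

# Studentized-range pairwise tests computed from first principles.
tukey_oracle <- function(design) {
  n <- nrow(design); k <- ncol(design)
  df <- data.frame(y = as.vector(design),
                   subj = rep(seq_len(n), k),
                   cond = rep(seq_len(k), each = n))
  grand <- mean(df$y)
  ss_total <- sum((df$y - grand)^2)
  ss_cond <- sum(tapply(df$y, df$cond, function(v) length(v) * (mean(v) - grand)^2))
  ss_subj <- sum(tapply(df$y, df$subj, function(v) length(v) * (mean(v) - grand)^2))
  dfe <- (n - 1) * (k - 1)
  mse <- (ss_total - ss_cond - ss_subj) / dfe
  m <- tapply(df$y, df$cond, mean)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    q <- abs(m[i] - m[j]) / sqrt(mse / n)
    out <- rbind(out, data.frame(i = i, j = j, q = q,
                                 p = ptukey(q, k, dfe, lower.tail = FALSE)))
  }
  out
}

# Per-element counting oracle for confusion-matrix metrics.
metrics_count_oracle <- function(true, pred, levels) {
  acc <- mean(true == pred)
  per <- lapply(levels, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f1, support = sum(true == cl))
  })
  per <- do.call(rbind, per)
  list(accuracy = acc, per_class = per,
       macro_f1 = mean(per[, "f1"]),
       weighted_f1 = sum(per[, "f1"] * per[, "support"]) / sum(per[, "support"]))
}

# Small deterministic feature tables for CV-machinery tests: three
# well-separated Gaussian classes, several participants, windowed rows.
make_toy_tables <- function(n_participants = 10, trials_per_class = 5,
                            n_windows = 4, effect = 2, seed = 99,
                            n_features = 11) {
  set.seed(seed)
  classes <- c("positive", "neutral", "negative")
  shift <- c(positive = effect, neutral = 0, negative = -effect)
  trial_rows <- list(); win_rows <- list()
  tid <- 0
  fnames <- FEATURE_NAMES[seq_len(n_features)]
  for (p in seq_len(n_participants)) {
    for (cl in classes) for (r in seq_len(trials_per_class)) {
      tid <- tid + 1
      base <- rnorm(n_features, 0, 1)
      base[1:3] <- base[1:3] + shift[cl]       # informative features
      tl <- data.frame(participant = p, trial = tid, label = cl,
                       window_index = -1L)
      tl[fnames] <- as.list(base)
      trial_rows[[tid]] <- tl
      for (wi in seq_len(n_windows)) {
        wr <- data.frame(participant = p, trial = tid, label = cl,
                         window_index = wi - 1L)
        wr[fnames] <- as.list(base + rnorm(n_features, 0, 0.3))
        win_rows[[length(win_rows) + 1]] <- wr
      }
    }
  }
  list(trial_table = do.call(rbind, trial_rows),
       window_table = do.call(rbind, win_rows))
}
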