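# Nested stratified five-fold cross-validation with fold-embedded feature
# screening, classification metrics and model comparison.

CLASS_LEVELS <- c("positive", "neutral", "negative")

#' Stratified cross-validation folds
#'
#' Class-stratified partition: within each class, trials are shuffled
#' (seeded) and dealt round-robin, so per-class fold sizes differ by at
#' most one.
#'
#' @param labels class label per trial.
#' @param n_folds number of folds (default 5).
#' @param seed RNG seed.
#' @return integer fold assignment (1..n_folds) per trial.
#' @export
make_folds <- function(labels, n_folds = 5, seed = 1L) {
  labels <- as.character(labels)
  if (any(table(labels) < n_folds)) stop("each class needs >= n_folds trials")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 5L))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Stratified validation split: returns logical "is validation" over idx.
stratified_val_split <- function(labels, frac, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 9L))
  is_val <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    n_val <- max(1L, round(frac * length(idx)))
    is_val[idx[sample.int(length(idx), n_val)]] <- TRUE
  }
  is_val
}

#' Confusion matrix
#'
#' @param true,pred class labels.
#' @param levels row/column order.
#' @return k x k integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(true, pred, levels = CLASS_LEVELS) {
  table(factor(as.character(true), levels),
        factor(as.character(pred), levels))
}

#' Harmonic-mean F1 score
#'
#' @param precision,recall per-class precision and recall.
#' @return F1 = 2PR/(P+R); 0 when both are 0.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Classification metrics from a confusion matrix
#'
#' Per-class one-vs-rest precision, recall and F1; overall accuracy; macro
#' F1 (unweighted mean of the per-class F1) and support-weighted F1.
#' Undefined precision (no predictions of a class) is reported as 0 and
#' flagged.
#'
#' @param cm confusion matrix (rows = true, columns = predicted).
#' @return list: `accuracy`, `per_class` (data.frame), `macro_f1`,
#'   `weighted_f1`, `undefined_precision` (character).
#' @export
compute_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  undef <- rownames(cm)[predicted == 0]
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- f1_score(precision, recall)
  list(accuracy = sum(tp) / total,
       per_class = data.frame(class = rownames(cm), precision = precision,
                              recall = recall, f1 = f1, support = support,
                              row.names = NULL),
       macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * support) / sum(support),
       undefined_precision = undef)
}

# Median-impute NAs per column using reference (training) medians.
impute_median <- function(M, medians = NULL) {
  M <- as.matrix(M)
  if (is.null(medians)) {
    medians <- apply(M, 2, stats::median, na.rm = TRUE)
  }
  for (j in seq_len(ncol(M))) {
    nas <- is.na(M[, j])
    if (any(nas)) M[nas, j] <- medians[j]
  }
  list(M = M, medians = medians)
}

# Build an n_trials x T x k array of PCA scores from a windowed table.
windows_to_array <- function(win_tab, trial_ids, features, center, scale,
                             pca, medians) {
  Tn <- length(unique(win_tab$window_index))
  arr <- array(NA_real_, c(length(trial_ids), Tn, pca$k))
  for (i in seq_along(trial_ids)) {
    rows <- win_tab[win_tab$trial == trial_ids[i], ]
    rows <- rows[order(rows$window_index), ]
    M <- impute_median(as.matrix(rows[, features, drop = FALSE]), medians)$M
    Z <- transform_pca(pca, sweep(sweep(M, 2, center), 2, scale, "/"))
    arr[i, , ] <- Z
  }
  arr
}

#' Nested cross-validated evaluation of the PCA-LSTM model and baselines
#'
#' For every outer fold: repeated-measures ANOVA screening on the training
#' trials only; feature standardization and PCA (90% cumulative variance)
#' fitted on training windows only; LSTM trained on the training portion
#' with a stratified 15% validation carve-out for scheduling/early
#' stopping; baselines trained on the same training inputs (sequence-mean
#' PCA scores); evaluation on the untouched test fold.
#'
#' @param trial_tab trial-level feature table (from
#'   [extract_features_experiment()]).
#' @param window_tab windowed feature table.
#' @param models subset of c("lstm", "svm", "rf", "knn", "xgb").
#' @param n_folds outer folds (default 5).
#' @param alpha screening level (default 0.05).
#' @param var_threshold PCA cumulative-variance criterion (default 0.90).
#' @param val_frac validation fraction of the training portion (default
#'   0.15).
#' @param train_cfg a [train_config()]; its seed is re-derived per fold.
#' @param seed master seed (folds, splits, per-fold training seeds).
#' @param permute_labels permuted-label control: trial labels are shuffled
#'   (seeded) before any analysis.
#' @return `cv_result` list: `folds` (per fold: selected features, k,
#'   screening table, per-model confusion matrix and metrics, LSTM weights
#'   and history), `accuracy` (model x fold matrix), `summary`
#'   (mean and n-1 SD accuracy per model), `fold_assignment`.
#' @export
run_nested_cv <- function(trial_tab, window_tab,
                          models = c("lstm", "svm", "rf", "knn", "xgb"),
                          n_folds = 5, alpha = 0.05, var_threshold = 0.90,
                          val_frac = 0.15, train_cfg = train_config(),
                          seed = 1L, permute_labels = FALSE) {
  stopifnot(all(models %in% c("lstm", "svm", "rf", "knn", "xgb")))
  trial_tab <- trial_tab[order(trial_tab$trial), ]
  if (permute_labels) {
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, 333L))
    trial_tab$label <- sample(trial_tab$label)
    .Random.seed_restore(old)
    window_tab$label <- trial_tab$label[match(window_tab$trial, trial_tab$trial)]
  }
  fold <- make_folds(trial_tab$label, n_folds, seed)
  acc <- matrix(NA_real_, length(models), n_folds,
                dimnames = list(models, paste0("fold", seq_len(n_folds))))
  folds_out <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train_ids <- trial_tab$trial[fold != f]
    test_ids <- trial_tab$trial[fold == f]
    train_trials <- trial_tab[fold != f, ]
    # --- screening: training rows only
    scr <- screen_features(train_trials, alpha = alpha)
    feats <- scr$selected
    # --- standardization + PCA on training windows only
    wt_train <- window_tab[window_tab$trial %in% train_ids, ]
    imp <- impute_median(as.matrix(wt_train[, feats, drop = FALSE]))
    center <- colMeans(imp$M)
    scale_ <- apply(imp$M, 2, stats::sd)
    scale_[scale_ < 1e-12] <- 1
    Xw <- sweep(sweep(imp$M, 2, center), 2, scale_, "/")
    pca <- fit_pca(Xw, var_threshold = var_threshold)

    arr_train <- windows_to_array(window_tab, train_ids, feats, center,
                                  scale_, pca, imp$medians)
    arr_test <- windows_to_array(window_tab, test_ids, feats, center,
                                 scale_, pca, imp$medians)
    y_train <- factor(train_trials$label, CLASS_LEVELS)
    y_test <- factor(trial_tab$label[fold == f], CLASS_LEVELS)

    is_val <- stratified_val_split(as.character(y_train), val_frac,
                                   derive_seed(seed, 21L, f))
    fold_res <- list(selected = feats, screening = scr$table,
                     fallback = scr$fallback, k = pca$k,
                     cumvar_k = pca$cumvar_k, pca = pca,
                     models = list())
    for (m in models) {
      if (m == "lstm") {
        cfg <- train_cfg
        cfg$seed <- derive_seed(seed, 41L, f)
        tr <- train_lstm(arr_train[!is_val, , , drop = FALSE],
                         y_train[!is_val],
                         arr_train[is_val, , , drop = FALSE],
                         y_train[is_val], cfg)
        pred_int <- predict_lstm(tr$weights, arr_test)$pred
        pred <- factor(levels(y_train)[pred_int], CLASS_LEVELS)
        fold_res$lstm_weights <- tr$weights
        fold_res$lstm_history <- tr$history
      } else {
        Xtr <- apply(arr_train[!is_val, , , drop = FALSE], c(1, 3), mean)
        Xte <- apply(arr_test, c(1, 3), mean)
        bm <- train_baseline(m, Xtr, as.character(y_train[!is_val]),
                             seed = derive_seed(seed, 51L, f, match(m, models)))
        pred <- predict_baseline(bm, Xte)
        pred <- factor(as.character(pred), CLASS_LEVELS)
      }
      cm <- confusion_matrix(y_test, pred)
      met <- compute_metrics(cm)
      acc[m, f] <- met$accuracy
      fold_res$models[[m]] <- list(cm = cm, metrics = met)
    }
    folds_out[[f]] <- fold_res
  }
  summary <- data.frame(model = rownames(acc),
                        mean_accuracy = rowMeans(acc),
                        sd_accuracy = apply(acc, 1, stats::sd),  # n-1
                        row.names = NULL)
  structure(list(folds = folds_out, accuracy = acc, summary = summary,
                 fold_assignment = fold, permuted = permute_labels),
            class = "cv_result")
}

#' Pool per-fold confusion matrices and per-class metrics
#'
#' @param cv a [run_nested_cv()] result.
#' @param model model name (default "lstm").
#' @return list: `cm` (summed confusion matrix), `metrics`
#'   (from [compute_metrics()]).
#' @export
pooled_metrics <- function(cv, model = "lstm") {
  cms <- lapply(cv$folds, function(f) f$models[[model]]$cm)
  cm <- Reduce(`+`, cms)
  list(cm = cm, metrics = compute_metrics(cm))
}

#' Paired model comparison over folds
#'
#' Paired t-tests on fold-wise accuracy differences against a reference
#' model, with 95% t confidence intervals, Bonferroni correction over the
#' comparisons, and paired Cohen's d (mean difference / SD of differences).
#'
#' @param acc model x fold accuracy matrix (as in `cv_result$accuracy`).
#' @param reference reference model name (default "lstm").
#' @param percent report differences in percentage points (default TRUE).
#' @return data.frame: comparison, difference, ci_lo, ci_hi, t, p, p_adj,
#'   d.
#' @export
compare_models <- function(acc, reference = "lstm", percent = TRUE) {
  stopifnot(reference %in% rownames(acc))
  others <- setdiff(rownames(acc), reference)
  m <- length(others)
  mult <- if (percent) 100 else 1
  rows <- lapply(others, function(o) {
    d <- (acc[reference, ] - acc[o, ]) * mult
    n <- length(d)
    md <- mean(d); sdd <- stats::sd(d)
    if (sdd < 1e-12) {
      return(data.frame(comparison = paste(reference, "vs", o),
                        difference = md, ci_lo = md, ci_hi = md,
                        t = NA_real_, p = NA_real_, p_adj = NA_real_,
                        d = if (md == 0) 0 else NA_real_))
    }
    se <- sdd / sqrt(n)
    tv <- md / se
    tc <- stats::qt(0.975, n - 1)
    p <- 2 * stats::pt(abs(tv), n - 1, lower.tail = FALSE)
    data.frame(comparison = paste(reference, "vs", o), difference = md,
               ci_lo = md - tc * se, ci_hi = md + tc * se, t = tv, p = p,
               p_adj = pmin(1, m * p), d = md / sdd)
  })
  do.call(rbind, rows)
}
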