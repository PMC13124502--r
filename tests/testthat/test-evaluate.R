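# Cross-validation machinery: stratified folds, metrics, nested evaluation
# without leakage, and paired model comparison.

test_that("stratified folds partition trials with balanced classes", {
  labels <- rep(c("positive", "neutral", "negative"), each = 120)
  f <- make_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(unname(table(labels[f == k])), rep(24L, 3),
                 ignore_attr = TRUE)
  }
  expect_identical(make_folds(labels, 5, seed = 3), f)
  expect_false(identical(make_folds(labels, 5, seed = 4), f))

  # non-divisible counts differ by at most one per class
  lab2 <- rep(c("positive", "neutral", "negative"), each = 23)
  f2 <- make_folds(lab2, 5, seed = 1)
  for (cl in unique(lab2)) {
    sizes <- table(f2[lab2 == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(make_folds(rep("positive", 3), 5), "n_folds")
})

test_that("metrics agree exactly with a per-element counting oracle", {
  lv <- c("positive", "neutral", "negative")
  cm <- matrix(c(8, 1, 1, 2, 7, 1, 0, 1, 9), 3, byrow = TRUE,
               dimnames = list(lv, lv))
  met <- compute_metrics(cm)
  expect_equal(met$accuracy, 24 / 30)

  d <- diag(c(5, 6, 7)); dimnames(d) <- list(lv, lv)
  md <- compute_metrics(d)
  expect_equal(md$accuracy, 1)
  expect_equal(md$per_class$f1, rep(1, 3))
  expect_equal(md$macro_f1, 1)

  for (s in 1:200) {
    set.seed(s)
    n <- sample(20:60, 1)
    true <- sample(lv, n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, true, sample(lv, n, replace = TRUE))
    got <- compute_metrics(confusion_matrix(true, pred, lv))
    want <- metrics_count_oracle(true, pred, lv)
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$per_class$precision, unname(want$per_class[, "precision"]))
    expect_equal(got$per_class$recall, unname(want$per_class[, "recall"]))
    expect_equal(got$per_class$f1, unname(want$per_class[, "f1"]))
    expect_equal(got$macro_f1, want$macro_f1)
    expect_equal(got$weighted_f1, want$weighted_f1)
  }
  expect_error(compute_metrics(matrix(0, 3, 3)), "empty")
})

test_that("weighted F1 equals macro F1 on balanced supports", {
  lv <- c("positive", "neutral", "negative")
  set.seed(9)
  true <- rep(lv, each = 40)
  pred <- ifelse(runif(120) < 0.7, true, sample(lv, 120, replace = TRUE))
  met <- compute_metrics(confusion_matrix(true, pred, lv))
  expect_equal(met$weighted_f1, met$macro_f1, tolerance = 1e-12)
})

test_that("undefined precision is reported as zero and flagged", {
  lv <- c("positive", "neutral", "negative")
  cm <- matrix(c(5, 5, 0, 3, 7, 0, 2, 8, 0), 3, byrow = TRUE,
               dimnames = list(lv, lv))
  met <- compute_metrics(cm)
  expect_equal(met$per_class$precision[3], 0)
  expect_equal(met$undefined_precision, "negative")
})

test_that("paired comparisons reproduce hand-computed statistics", {
  acc <- rbind(lstm = c(0.9, 0.92, 0.93, 0.94, 0.95),
               svm = c(0.89, 0.90, 0.90, 0.90, 0.92))
  acc["svm", ] <- acc["lstm", ] - c(1, 2, 3, 4, 5) / 100
  cmp <- compare_models(acc, reference = "lstm")
  expect_equal(cmp$difference, 3)
  expect_equal(cmp$t, 3 / (sd(1:5) / sqrt(5)), tolerance = 1e-6)
  expect_equal(cmp$t, 4.2426, tolerance = 1e-4)
  expect_equal(cmp$d, 3 / sd(1:5), tolerance = 1e-6)
  expect_equal(cmp$d, 1.8974, tolerance = 1e-4)
  expect_equal(cmp$p_adj, pmin(1, 1 * cmp$p))  # one comparison here

  same <- rbind(lstm = rep(0.9, 5), rf = rep(0.9, 5))
  c2 <- compare_models(same)
  expect_equal(c2$difference, 0)
  expect_equal(c2$d, 0)

  acc4 <- rbind(lstm = c(0.9, 0.92, 0.91, 0.95, 0.94),
                svm = c(0.8, 0.82, 0.81, 0.80, 0.86),
                rf = c(0.85, 0.80, 0.84, 0.83, 0.86),
                knn = c(0.70, 0.75, 0.72, 0.78, 0.74),
                xgb = c(0.88, 0.85, 0.86, 0.84, 0.90))
  c4 <- compare_models(acc4)
  expect_equal(c4$p_adj, pmin(1, 4 * c4$p))
})

test_that("nested CV partitions trials and stays leakage-free", {
  toy <- make_toy_tables(n_participants = 8, trials_per_class = 5,
                         effect = 1.8, seed = 77)
  cfg <- train_config(hidden = 12, fc = c(12, 8, 6), max_epochs = 25)
  cv <- run_nested_cv(toy$trial_table, toy$window_table,
                      models = c("lstm", "rf"), train_cfg = cfg, seed = 5)
  # partition: every trial tested exactly once
  tested <- unlist(lapply(1:5, function(f) {
    toy$trial_table$trial[cv$fold_assignment == f]
  }))
  expect_setequal(tested, toy$trial_table$trial)
  total_support <- sum(vapply(cv$folds,
                              function(f) sum(f$models$lstm$cm), numeric(1)))
  expect_equal(total_support, nrow(toy$trial_table))
  expect_true(all(cv$accuracy >= 0 & cv$accuracy <= 1))
  # separable toy problem: well above chance
  expect_gt(cv$summary$mean_accuracy[cv$summary$model == "lstm"], 0.7)

  # leakage sentinel: corrupt every test-fold row after the (seeded) split
  fold <- make_folds(toy$trial_table$label, 5, seed = 5)
  test_ids <- toy$trial_table$trial[fold == 1]
  tt2 <- toy$trial_table
  wt2 <- toy$window_table
  feat <- FEATURE_NAMES
  tt2[tt2$trial %in% test_ids, feat] <- 1e6
  wt2[wt2$trial %in% test_ids, feat] <- 1e6
  cv2 <- run_nested_cv(tt2, wt2, models = c("lstm", "rf"),
                       train_cfg = cfg, seed = 5)
  expect_identical(cv2$folds[[1]]$screening, cv$folds[[1]]$screening)
  expect_identical(cv2$folds[[1]]$selected, cv$folds[[1]]$selected)
  expect_identical(cv2$folds[[1]]$pca, cv$folds[[1]]$pca)
  expect_identical(cv2$folds[[1]]$lstm_weights, cv$folds[[1]]$lstm_weights)
})

test_that("undefined feature values are median-imputed inside the fold", {
  toy <- make_toy_tables(n_participants = 6, trials_per_class = 4,
                         effect = 2, seed = 80)
  # knock out scattered values in one feature across both tables
  set.seed(81)
  toy$trial_table$SampEn[sample(nrow(toy$trial_table), 8)] <- NA
  toy$window_table$SampEn[sample(nrow(toy$window_table), 30)] <- NA
  cfg <- train_config(hidden = 8, fc = c(8, 6, 4), max_epochs = 10)
  cv <- run_nested_cv(toy$trial_table, toy$window_table,
                      models = c("lstm", "knn"), train_cfg = cfg, seed = 9)
  expect_true(all(is.finite(cv$accuracy)))
  expect_equal(sum(vapply(cv$folds, function(f) sum(f$models$lstm$cm),
                          numeric(1))), nrow(toy$trial_table))
})

test_that("permuted labels drive accuracy to chance on the toy problem", {
  toy <- make_toy_tables(n_participants = 8, trials_per_class = 5,
                         effect = 1.8, seed = 78)
  cfg <- train_config(hidden = 12, fc = c(12, 8, 6), max_epochs = 20)
  cvp <- run_nested_cv(toy$trial_table, toy$window_table, models = "lstm",
                       train_cfg = cfg, seed = 6, permute_labels = TRUE)
  expect_lt(cvp$summary$mean_accuracy, 0.55)
  expect_gt(cvp$summary$mean_accuracy, 0.15)
})

test_that("pooled metrics sum fold confusion matrices", {
  toy <- make_toy_tables(n_participants = 6, trials_per_class = 4,
                         effect = 2, seed = 79)
  cfg <- train_config(hidden = 8, fc = c(8, 6, 4), max_epochs = 15)
  cv <- run_nested_cv(toy$trial_table, toy$window_table, models = "lstm",
                      train_cfg = cfg, seed = 7)
  pm <- pooled_metrics(cv, "lstm")
  expect_equal(sum(pm$cm), nrow(toy$trial_table))
  expect_equal(unname(rowSums(pm$cm)), rep(24, 3), ignore_attr = TRUE)
})
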