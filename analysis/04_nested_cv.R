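#!/usr/bin/env Rscript
# Stage 4 — nested stratified five-fold cross-validation of the PCA-LSTM
# classifier and the four classical baselines (SVM, random forest, kNN,
# XGBoost), with ANOVA feature screening, standardization and PCA all
# refit inside each training fold. Also runs the permuted-label control
# for the sequence model.

library(emofuse)

trial_tab <- read_feature_table("results/features_trial.tsv")
window_tab <- read_feature_table("results/features_windows.tsv")

seed <- 1L
cv <- run_nested_cv(trial_tab, window_tab, seed = seed)
cmp <- compare_models(cv$accuracy)
write_run_report(cv, cmp, "results", seed = seed)

cat("mean accuracy over 5 folds (+/- SD):\n")
with(cv$summary, for (i in seq_along(model)) {
  cat(sprintf("  %-5s %.2f%% +/- %.2f%%\n", model[i],
              100 * mean_accuracy[i], 100 * sd_accuracy[i]))
})

cvp <- run_nested_cv(trial_tab, window_tab, models = "lstm", seed = seed,
                     permute_labels = TRUE)
cat(sprintf("permuted-label control (LSTM): %.2f%%\n",
            100 * cvp$summary$mean_accuracy))
jsonlite::write_json(
  list(permuted_accuracy = cvp$summary$mean_accuracy,
       real_accuracy = cv$summary$mean_accuracy[cv$summary$model == "lstm"]),
  "results/permutation_control.json", auto_unbox = TRUE, digits = NA)

pm <- pooled_metrics(cv, "lstm")
cat("\npooled confusion matrix (rows = true):\n")
print(pm$cm)
cat("\nper-class metrics:\n")
print(pm$metrics$per_class, digits = 3, row.names = FALSE)
utils::write.table(pm$metrics$per_class, "results/per_class_metrics.tsv",
                   sep = "\t", row.names = FALSE, quote = FALSE)
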