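#!/usr/bin/env Rscript
# Stage 5 — paired statistical comparison of the PCA-LSTM model against
# the four baselines over the shared cross-validation folds: paired
# t-tests on fold-wise accuracies, 95% confidence intervals, Bonferroni
# correction over the four comparisons and paired Cohen's d.

library(emofuse)

rep <- jsonlite::read_json("results/run_report.json", simplifyVector = TRUE)
acc <- rep$accuracy
rownames(acc) <- rep$summary$model

cmp <- compare_models(as.matrix(acc), reference = "lstm")
utils::write.table(cmp, "results/model_comparison.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

cat("paired comparisons (accuracy difference in percentage points):\n")
for (i in seq_len(nrow(cmp))) {
  cat(sprintf("  %-14s diff %5.2f  95%% CI [%5.2f, %5.2f]  t = %5.2f  p = %.4g  p_adj = %.4g  d = %.2f\n",
              cmp$comparison[i], cmp$difference[i], cmp$ci_lo[i],
              cmp$ci_hi[i], cmp$t[i], cmp$p[i], cmp$p_adj[i], cmp$d[i]))
}
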