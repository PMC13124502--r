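#!/usr/bin/env Rscript
# Stage 3 — group-level statistics: one-way repeated-measures ANOVA (with
# Greenhouse-Geisser correction) and Tukey HSD post-hoc tests for each of
# the 11 physiological features, on participant-condition means over the
# full trial-level table produced by 02_extract.R.

library(emofuse)

tab <- read_feature_table("results/features_trial.tsv")
gs <- group_stats(tab)

summary_tab <- do.call(rbind, lapply(names(gs), function(f) {
  a <- gs[[f]]$anova
  data.frame(feature = f, F = a$F, df1 = a$df1, df2 = a$df2,
             epsilon_GG = a$epsilon_GG, p_GG = a$p_GG, eta_sq = a$eta_sq,
             significant = gs[[f]]$significant)
}))
utils::write.table(summary_tab, "results/group_anova.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

posthoc_tab <- do.call(rbind, lapply(names(gs), function(f) {
  cbind(feature = f, gs[[f]]$posthoc)
}))
utils::write.table(posthoc_tab, "results/group_tukey.tsv", sep = "\t",
                   row.names = FALSE, quote = FALSE)

jsonlite::write_json(
  lapply(gs, function(g) list(anova = g$anova[c("F", "df1", "df2", "p",
                                                "epsilon_GG", "p_GG",
                                                "eta_sq")],
                              posthoc = g$posthoc,
                              significant = g$significant)),
  "results/group_stats.json", auto_unbox = TRUE, digits = NA)

cat("features with a significant condition effect (p_GG < 0.05):\n")
print(summary_tab[summary_tab$significant,
                  c("feature", "F", "p_GG", "eta_sq")],
      digits = 3, row.names = FALSE)
cat("\nnon-significant features:\n")
print(summary_tab$feature[!summary_tab$significant])
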