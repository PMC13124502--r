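# Repeated-measures ANOVA machinery: group-level physiological analyses
# and fold-embedded feature screening.

#' Build a participant x condition design matrix for one feature
#'
#' Aggregates trials to participant-level means per condition; participants
#' with any empty (or all-NA) cell are dropped.
#'
#' @param tab feature table (columns participant, label and the feature).
#' @param feature feature column name.
#' @param conditions condition levels (column order of the result).
#' @return n x k numeric matrix; attribute `"dropped"` lists removed
#'   participants.
#' @export
rm_design_matrix <- function(tab, feature,
                             conditions = c("positive", "neutral", "negative")) {
  agg <- tapply(tab[[feature]], list(tab$participant, factor(tab$label, conditions)),
                function(v) mean(v, na.rm = TRUE))
  agg <- matrix(agg, nrow = nrow(agg), dimnames = dimnames(agg))
  complete <- apply(agg, 1, function(r) all(is.finite(r)))
  out <- agg[complete, , drop = FALSE]
  if (nrow(out) < 3) stop("fewer than 3 participants with complete cells")
  attr(out, "dropped") <- rownames(agg)[!complete]
  out
}

# Greenhouse-Geisser epsilon from the sample covariance of the conditions.
gg_epsilon <- function(S) {
  k <- ncol(S)
  d_mean <- mean(diag(S))
  row_means <- rowMeans(S)
  grand <- mean(S)
  num <- (k * (d_mean - grand))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * grand^2)
  if (den <= 0) return(1)
  min(1, max(1 / (k - 1), num / den))
}

#' One-way repeated-measures ANOVA
#'
#' Classical within-subject partition with Greenhouse-Geisser correction:
#' `SS_error = SS_within - SS_subjects`, `F = MS_cond / MS_error` on
#' `(k-1, (n-1)(k-1))` degrees of freedom; the corrected p-value evaluates
#' F at epsilon-scaled dfs; the effect size is partial eta squared.
#'
#' @param design n participants x k conditions numeric matrix.
#' @return list: `F`, `df1`, `df2`, `p`, `epsilon_GG`, `p_GG`, `eta_sq`,
#'   `ms_error`, `df_error`, `n`, `means`. `F` is `NA` (degenerate) when
#'   the error variance is zero.
#' @export
rm_anova <- function(design) {
  design <- as.matrix(design)
  n <- nrow(design); k <- ncol(design)
  stopifnot(n >= 3, k >= 2, all(is.finite(design)))
  grand <- mean(design)
  cond_means <- colMeans(design)
  subj_means <- rowMeans(design)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_total <- sum((design - grand)^2)
  ss_error <- ss_total - ss_subj - ss_cond
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  ms_cond <- ss_cond / df1
  ms_error <- ss_error / df2
  eps <- gg_epsilon(stats::cov(design))
  if (ss_cond <= 1e-300 && ms_error <= 1e-300) {
    # no condition effect at all: F = 0 by convention
    return(list(F = 0, df1 = df1, df2 = df2, p = 1, epsilon_GG = eps,
                p_GG = 1, eta_sq = 0, ms_error = ms_error, df_error = df2,
                n = n, means = cond_means, degenerate = FALSE))
  }
  if (ms_error <= 1e-300) {
    return(list(F = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                epsilon_GG = eps, p_GG = NA_real_,
                eta_sq = if (ss_cond + ss_error > 0) ss_cond / (ss_cond + ss_error) else NA_real_,
                ms_error = ms_error, df_error = df2, n = n,
                means = cond_means, degenerate = TRUE))
  }
  Fv <- ms_cond / ms_error
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE),
       epsilon_GG = eps,
       p_GG = stats::pf(Fv, eps * df1, eps * df2, lower.tail = FALSE),
       eta_sq = ss_cond / (ss_cond + ss_error),
       ms_error = ms_error, df_error = df2, n = n,
       means = cond_means, degenerate = FALSE)
}

#' Tukey HSD post-hoc tests for a repeated-measures design
#'
#' Pairwise studentized-range tests using the omnibus error term:
#' `q = |m_i - m_j| / sqrt(MS_error / n)`, p-values from the studentized
#' range distribution with `k` groups and the omnibus error df.
#'
#' @param design n x k matrix (as for [rm_anova()]).
#' @param ms_error,df_error omnibus error mean square and df; computed from
#'   the design when omitted.
#' @return data.frame: `pair`, `difference`, `q`, `p`.
#' @export
tukey_hsd_rm <- function(design, ms_error = NULL, df_error = NULL) {
  design <- as.matrix(design)
  n <- nrow(design); k <- ncol(design)
  if (is.null(ms_error) || is.null(df_error)) {
    a <- rm_anova(design)
    ms_error <- a$ms_error; df_error <- a$df_error
  }
  m <- colMeans(design)
  cn <- colnames(design)
  if (is.null(cn)) cn <- paste0("C", seq_len(k))
  pairs <- utils::combn(k, 2)
  se <- sqrt(ms_error / n)
  out <- data.frame(
    pair = apply(pairs, 2, function(ij) paste(cn[ij[1]], "vs", cn[ij[2]])),
    difference = apply(pairs, 2, function(ij) m[ij[1]] - m[ij[2]])
  )
  if (ms_error <= 1e-300) {
    out$q <- NA_real_; out$p <- NA_real_
    return(out)
  }
  out$q <- abs(out$difference) / se
  out$p <- stats::ptukey(out$q, nmeans = k, df = df_error, lower.tail = FALSE)
  out
}

#' Fold-embedded feature screening
#'
#' Runs a repeated-measures ANOVA per feature on the training trials only
#' (participant-condition means) and selects the features whose
#' Greenhouse-Geisser corrected p-value is below `alpha`. If fewer than
#' two features pass, the three smallest-p features are selected instead
#' (logged in the result).
#'
#' @param training_tab trial-level feature table (training rows only).
#' @param alpha selection level (default 0.05).
#' @param features feature columns to screen.
#' @return list: `selected` (character), `table` (per-feature statistics),
#'   `fallback` (logical), `dropped_participants`.
#' @export
screen_features <- function(training_tab, alpha = 0.05,
                            features = FEATURE_NAMES) {
  stopifnot(all(c("positive", "neutral", "negative") %in% training_tab$label))
  dropped <- character(0)
  rows <- lapply(features, function(f) {
    dm <- rm_design_matrix(training_tab, f)
    dropped <<- union(dropped, attr(dm, "dropped"))
    a <- rm_anova(dm)
    data.frame(feature = f, F = a$F, df1 = a$df1, df2 = a$df2,
               p = a$p, epsilon_GG = a$epsilon_GG, p_GG = a$p_GG,
               eta_sq = a$eta_sq)
  })
  tab <- do.call(rbind, rows)
  tab$selected <- !is.na(tab$p_GG) & tab$p_GG < alpha
  fallback <- sum(tab$selected) < 2
  if (fallback) {
    ord <- order(tab$p_GG)
    tab$selected <- seq_len(nrow(tab)) %in% ord[1:3]
  }
  list(selected = tab$feature[tab$selected], table = tab,
       fallback = fallback, dropped_participants = dropped)
}

#' Categorize a video from its mean SAM ratings
#'
#' Strict selection thresholds: positive when valence > 7 and arousal > 6;
#' negative when valence < 3 and arousal > 6; neutral when valence in
#' \[4, 6\] and arousal < 4; otherwise "none".
#'
#' @param valence,arousal mean ratings on the 1-9 scale.
#' @return one of "positive", "negative", "neutral", "none".
#' @export
categorize_video <- function(valence, arousal) {
  stopifnot(valence >= 1, valence <= 9, arousal >= 1, arousal <= 9)
  if (valence > 7 && arousal > 6) return("positive")
  if (valence < 3 && arousal > 6) return("negative")
  if (valence >= 4 && valence <= 6 && arousal < 4) return("neutral")
  "none"
}

#' Group-level statistical report
#'
#' Repeated-measures ANOVA (with Greenhouse-Geisser correction) and Tukey
#' HSD post-hoc tests for each supplied measure, aggregated to
#' participant-condition means over the full trial-level table.
#'
#' @param trial_tab trial-level feature table; may also contain
#'   `sam_valence` / `sam_arousal` columns.
#' @param measures column names to analyse.
#' @param alpha significance level for the `significant` flag.
#' @return list per measure: `anova` (from [rm_anova()]), `posthoc` (from
#'   [tukey_hsd_rm()]), `significant`.
#' @export
group_stats <- function(trial_tab, measures = FEATURE_NAMES, alpha = 0.05) {
  if (length(unique(trial_tab$label)) < 2) stop("need at least two conditions")
  out <- lapply(measures, function(f) {
    dm <- rm_design_matrix(trial_tab, f)
    a <- rm_anova(dm)
    list(anova = a,
         posthoc = tukey_hsd_rm(dm, a$ms_error, a$df_error),
         significant = !is.na(a$p_GG) && a$p_GG < alpha)
  })
  names(out) <- measures
  out
}
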