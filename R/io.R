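# Plain-text interchange: trial sets as per-modality CSV + JSON ground
# truth + TSV manifest; feature tables as TSV; run reports as JSON and
# markdown.

trial_stem <- function(tr) {
  sprintf("p%02d_t%03d", tr$participant_id, tr$trial_id)
}

#' Write a trial set to a directory
#'
#' One CSV per modality per trial (header `time_s,<channel>...`), a JSON
#' ground-truth/metadata file per trial, and a TSV manifest.
#'
#' @param trials list of `trial_record` objects (see
#'   [generate_experiment()]).
#' @param dir output directory (created if needed).
#' @return the manifest data.frame, invisibly.
#' @export
write_trial_set <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mrows <- lapply(trials, function(tr) {
    stem <- trial_stem(tr)
    eeg <- data.frame(time_s = seq_len(nrow(tr$eeg)) / tr$eeg_fs, tr$eeg)
    utils::write.csv(eeg, file.path(dir, paste0(stem, "_eeg.csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(time_s = seq_along(tr$ecg) / tr$ecg_fs, ECG = tr$ecg),
      file.path(dir, paste0(stem, "_ecg.csv")), row.names = FALSE)
    utils::write.csv(
      data.frame(time_s = seq_along(tr$gsr) / tr$gsr_fs, GSR = tr$gsr),
      file.path(dir, paste0(stem, "_gsr.csv")), row.names = FALSE)
    meta <- list(participant_id = tr$participant_id, trial_id = tr$trial_id,
                 label = tr$label, rep = tr$rep,
                 eeg_fs = tr$eeg_fs, ecg_fs = tr$ecg_fs, gsr_fs = tr$gsr_fs,
                 sam_valence = tr$sam_valence, sam_arousal = tr$sam_arousal,
                 ground_truth = tr$ground_truth)
    jsonlite::write_json(meta, file.path(dir, paste0(stem, "_meta.json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(participant = tr$participant_id, trial = tr$trial_id,
               label = tr$label, valence = tr$sam_valence,
               arousal = tr$sam_arousal)
  })
  manifest <- do.call(rbind, mrows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a trial set written by [write_trial_set()]
#'
#' @param dir trial-set directory.
#' @return list of `trial_record` objects with the manifest attached as
#'   attribute `"manifest"`.
#' @export
read_trial_set <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv in ", dir)
  manifest <- utils::read.delim(mpath)
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    stem <- sprintf("p%02d_t%03d", manifest$participant[i], manifest$trial[i])
    meta <- jsonlite::read_json(file.path(dir, paste0(stem, "_meta.json")),
                                simplifyVector = TRUE)
    # empty JSON arrays come back as lists; restore typed vectors
    gt <- meta$ground_truth
    gt$r_peaks <- as.integer(unlist(gt$r_peaks))
    gt$scr_onsets_s <- as.numeric(unlist(gt$scr_onsets_s))
    gt$scr_amplitudes <- as.numeric(unlist(gt$scr_amplitudes))
    gt$rr_ms <- as.numeric(unlist(gt$rr_ms))
    gt$ectopic <- as.logical(unlist(gt$ectopic))
    gt$ai_true <- unlist(gt$ai_true)
    meta$ground_truth <- gt
    eeg <- utils::read.csv(file.path(dir, paste0(stem, "_eeg.csv")))
    ecg <- utils::read.csv(file.path(dir, paste0(stem, "_ecg.csv")))
    gsr <- utils::read.csv(file.path(dir, paste0(stem, "_gsr.csv")))
    structure(list(participant_id = meta$participant_id,
                   trial_id = meta$trial_id, label = meta$label,
                   rep = meta$rep,
                   eeg = as.matrix(eeg[, -1]), ecg = ecg$ECG, gsr = gsr$GSR,
                   eeg_fs = meta$eeg_fs, ecg_fs = meta$ecg_fs,
                   gsr_fs = meta$gsr_fs,
                   sam_valence = meta$sam_valence,
                   sam_arousal = meta$sam_arousal,
                   ground_truth = meta$ground_truth),
              class = "trial_record")
  })
  attr(trials, "manifest") <- manifest
  trials
}

#' Write feature tables as TSV
#'
#' @param fx result of [extract_features_experiment()].
#' @param dir output directory.
#' @return invisibly, the file paths.
#' @export
write_feature_tables <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(trial = file.path(dir, "features_trial.tsv"),
             window = file.path(dir, "features_windows.tsv"),
             exclusions = file.path(dir, "exclusions.tsv"))
  utils::write.table(fx$trial_table, paths["trial"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fx$window_table, paths["window"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(fx$exclusions, paths["exclusions"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a feature table TSV
#'
#' @param path file written by [write_feature_tables()].
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a cross-validation run report
#'
#' JSON report with per-fold selections, retained dimensionality,
#' confusion matrices and metrics, the model-comparison table, and a
#' provenance block (seed, package and R versions); plus a human-readable
#' markdown summary.
#'
#' @param cv a [run_nested_cv()] result.
#' @param comparison optional [compare_models()] table.
#' @param dir output directory.
#' @param seed the master seed used for the run (recorded as provenance).
#' @return invisibly, the JSON path.
#' @export
write_run_report <- function(cv, comparison = NULL, dir, seed = NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  folds <- lapply(cv$folds, function(f) {
    list(selected = f$selected, k = f$k, cumvar_k = f$cumvar_k,
         fallback = f$fallback,
         models = lapply(f$models, function(m) {
           list(confusion = unclass(m$cm),
                accuracy = m$metrics$accuracy,
                per_class = m$metrics$per_class,
                macro_f1 = m$metrics$macro_f1,
                weighted_f1 = m$metrics$weighted_f1)
         }))
  })
  report <- list(
    provenance = list(seed = seed,
                      package_version = as.character(utils::packageVersion("emofuse")),
                      r_version = R.version.string,
                      permuted_labels = cv$permuted),
    summary = cv$summary,
    accuracy = cv$accuracy,
    folds = folds,
    comparison = comparison)
  jpath <- file.path(dir, "run_report.json")
  jsonlite::write_json(report, jpath, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  md <- c("# Nested cross-validation report", "",
          sprintf("- seed: %s", seed),
          sprintf("- permuted labels: %s", cv$permuted), "",
          "## Accuracy (mean +/- SD over folds)", "",
          sprintf("- %s: %.2f%% +/- %.2f%%", cv$summary$model,
                  100 * cv$summary$mean_accuracy,
                  100 * cv$summary$sd_accuracy))
  if (!is.null(comparison)) {
    md <- c(md, "", "## Paired comparisons (accuracy, percentage points)", "",
            sprintf("- %s: diff %.2f [%.2f, %.2f], t = %.2f, p = %.4g, p_adj = %.4g, d = %.2f",
                    comparison$comparison, comparison$difference,
                    comparison$ci_lo, comparison$ci_hi, comparison$t,
                    comparison$p, comparison$p_adj, comparison$d))
  }
  writeLines(md, file.path(dir, "run_report.md"))
  invisible(jpath)
}
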