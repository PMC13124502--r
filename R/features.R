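# Trial-level and windowed feature extraction: three frontal alpha
# asymmetry indices, six HRV indices, two electrodermal indices.

FEATURE_NAMES <- c("AI_Fp2Fp1", "AI_F4F3", "AI_F8F7",
                   "SDNN", "RMSSD", "LF", "HF", "LF_HF", "SampEn",
                   "SCL", "NS_SCRs")

#' Frontal alpha asymmetry index
#'
#' `AI = ln(P_right) - ln(P_left)` for the alpha-band powers of a
#' homologous electrode pair.
#'
#' @param p_right,p_left alpha powers (same units); must be positive.
#' @return asymmetry index (dimensionless), `NA` if either power is
#'   non-positive.
#' @export
asymmetry_index <- function(p_right, p_left) {
  if (!is.finite(p_right) || !is.finite(p_left) ||
      p_right <= 0 || p_left <= 0) {
    return(NA_real_)
  }
  log(p_right) - log(p_left)
}

#' Time-domain HRV indices
#'
#' SDNN (sample SD, n-1 denominator) and RMSSD (root mean square of
#' successive differences) of an NN series.
#'
#' @param nn NN intervals (ms), >= 10 values.
#' @return named numeric: `SDNN`, `RMSSD` (ms); `NA`s if too short.
#' @export
hrv_time <- function(nn) {
  if (length(nn) < 10) return(c(SDNN = NA_real_, RMSSD = NA_real_))
  c(SDNN = stats::sd(nn), RMSSD = sqrt(mean(diff(nn)^2)))
}

#' Frequency-domain HRV indices
#'
#' The NN tachogram is cubic-spline resampled at 4 Hz and its Welch PSD
#' (64 s Hann segments, 50% overlap, or the full length when shorter)
#' integrated over the LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands.
#'
#' @param nn NN intervals (ms).
#' @param beat_times_s optional beat times (s) aligned with `nn`; defaults
#'   to the cumulative sum of the intervals.
#' @return named numeric: `LF`, `HF` (ms^2), `LF_HF` (`NA` when HF = 0).
#' @export
hrv_freq <- function(nn, beat_times_s = NULL) {
  if (is.null(beat_times_s)) beat_times_s <- cumsum(nn) / 1000
  span <- beat_times_s[length(beat_times_s)] - beat_times_s[1]
  if (span < 45) return(c(LF = NA_real_, HF = NA_real_, LF_HF = NA_real_))
  fs_r <- 4
  grid <- seq(beat_times_s[1], beat_times_s[length(beat_times_s)], by = 1 / fs_r)
  tach <- stats::spline(beat_times_s, nn, xout = grid)$y
  psd <- welch_psd(tach - mean(tach), fs_r, seg_len_s = 64)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.40)
  c(LF = lf, HF = hf, LF_HF = if (hf > 0) lf / hf else NA_real_)
}

#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` counts pairs of length-`m` templates
#' within Chebyshev distance `r` and `A` the same for length-`m+1`
#' templates (self-matches excluded; templates taken at the `n - m` common
#' starting points).
#'
#' @param x numeric series.
#' @param m embedding dimension (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return sample entropy, `NA` if undefined (no matches or degenerate
#'   input).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  n <- length(x)
  if (n < m + 2 || !is.finite(r) || r < 0) return(NA_real_)
  if (r == 0) r <- .Machine$double.eps  # constant series: exact ties match
  count_pairs <- function(dim) {
    nt <- n - m  # common template count for both dimensions
    emb <- sapply(seq_len(dim), function(k) x[(k):(k + nt - 1)])
    emb <- matrix(emb, nrow = nt)
    within <- matrix(TRUE, nt, nt)
    for (k in seq_len(dim)) {
      dk <- abs(outer(emb[, k], emb[, k], "-")) <= r
      within <- within & dk
    }
    (sum(within) - nt) / 2  # unordered pairs, self-matches excluded
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Tonic skin conductance level of a window
#'
#' Mean of the Z-scored, low-passed conductance over the window.
#'
#' @param z numeric normalized GSR samples.
#' @return SCL in z-units.
#' @export
scl <- function(z) {
  if (!length(z)) stop("empty window")
  mean(z)
}

#' Count non-specific skin conductance responses
#'
#' Trough-to-peak detection on the low-passed conductance signal: a
#' response is a local maximum whose rise above the minimum of the
#' preceding 5 s is at least `threshold_us` in raw microsiemens (converted
#' via the stored normalization SD), confirmed by a decline of at least
#' half the threshold within the following 3 s (rejecting inflections that
#' ride a larger rise). Tonic drift does not qualify: near a drift crest
#' the 5 s rise and subsequent decline are far below threshold.
#'
#' @param z normalized GSR samples (one window, >= 10 s).
#' @param fs sampling rate (Hz).
#' @param sd_raw raw-unit normalization SD (microsiemens per z-unit);
#'   use 1 if `z` is in raw units.
#' @param threshold_us minimum amplitude (microsiemens), default 0.01.
#' @return integer count.
#' @export
ns_scrs <- function(z, fs, sd_raw = 1, threshold_us = 0.01) {
  stopifnot(length(z) >= 10 * fs)
  n <- length(z)
  ds <- diff(sign(diff(z)))
  maxima <- which(ds < 0) + 1L
  if (!length(maxima)) return(0L)
  thr_z <- threshold_us / sd_raw
  w_rise <- round(5 * fs)
  w_fall <- round(3 * fs)
  w_sep <- round(5.5 * fs)
  cand <- maxima[vapply(maxima, function(m) {
    trough <- min(z[max(1L, m - w_rise):m])
    fall_min <- min(z[m:min(n, m + w_fall)])
    z[m] - trough >= thr_z && z[m] - fall_min >= thr_z / 2
  }, logical(1))]
  # merge qualifying peaks closer than 5.5 s, keeping the larger: removes
  # zero-phase filter ringing satellites and inflections riding one
  # response (distinct responses are resolvable only beyond this scale
  # after a 0.3 Hz low-pass)
  accepted <- integer(0)
  for (m in cand) {
    if (length(accepted) && m - accepted[length(accepted)] < w_sep) {
      if (z[m] > z[accepted[length(accepted)]]) accepted[length(accepted)] <- m
    } else {
      accepted <- c(accepted, m)
    }
  }
  length(accepted)
}

# Window start/end times (s) for a trial of given duration.
feature_windows <- function(duration, window_s, hop_s) {
  n_win <- floor((duration - window_s) / hop_s) + 1
  if (n_win < 1) stop("window longer than trial")
  starts <- (seq_len(n_win) - 1) * hop_s
  data.frame(start = starts, end = starts + window_s)
}

# Compute the 11 features over one time window.
window_features <- function(alpha128, nn, nn_times, gsr_z, gsr_fs, gsr_sd,
                            t0, t1, sampen_m = 2, sampen_r_frac = 0.2) {
  # EEG: alpha power of the wavelet reconstruction restricted to the window
  idx <- (floor(t0 * 128) + 1):min(floor(t1 * 128), nrow(alpha128))
  pw <- colMeans(alpha128[idx, , drop = FALSE]^2)
  ai <- c(AI_Fp2Fp1 = asymmetry_index(pw["FP2"], pw["FP1"]),
          AI_F4F3 = asymmetry_index(pw["F4"], pw["F3"]),
          AI_F8F7 = asymmetry_index(pw["F8"], pw["F7"]))
  names(ai) <- c("AI_Fp2Fp1", "AI_F4F3", "AI_F8F7")
  # HRV on the NN intervals whose beat falls in the window
  sel <- nn_times > t0 & nn_times <= t1
  nn_w <- nn[sel]
  ht <- hrv_time(nn_w)
  hf <- if (sum(sel) >= 4) hrv_freq(nn_w, nn_times[sel]) else
    c(LF = NA_real_, HF = NA_real_, LF_HF = NA_real_)
  se <- if (length(nn_w) >= sampen_m + 2 && stats::sd(nn_w) > 0) {
    sample_entropy(nn_w, m = sampen_m, r = sampen_r_frac * stats::sd(nn_w))
  } else NA_real_
  # GSR
  gidx <- (floor(t0 * gsr_fs) + 1):min(floor(t1 * gsr_fs), length(gsr_z))
  gz <- gsr_z[gidx]
  out <- c(ai, ht, hf, SampEn = se, SCL = scl(gz),
           NS_SCRs = as.numeric(ns_scrs(gz, gsr_fs, sd_raw = gsr_sd)))
  out[FEATURE_NAMES]
}

#' Extract the multimodal feature set of one trial
#'
#' Preprocesses all three modalities and computes the 11-dimensional
#' feature vector both over the full trial and over a sliding-window
#' sequence (defaults 60 s window, 20 s hop: 4 steps on a 120 s trial).
#'
#' @param trial a `trial_record` (see [simulate_trial()]) or any list with
#'   the same fields.
#' @param gsr_stats participant-pooled normalization constants from
#'   [participant_gsr_stats()]; when `NULL` the trial's own statistics are
#'   used.
#' @param window_s,hop_s sequence window length and hop (s).
#' @return list: `trial` (named length-11 vector), `seq` (windows x 11
#'   matrix), `excluded` (logical), `reason`, `quality` (list with
#'   `n_corrected`, `bad_channels`, `low_quality_nn`).
#' @export
extract_features <- function(trial, gsr_stats = NULL,
                             window_s = 60, hop_s = 20) {
  duration <- length(trial$ecg) / trial$ecg_fs
  eeg <- preprocess_eeg(trial$eeg, trial$eeg_fs)
  if (eeg$rejected) {
    return(list(trial = NULL, seq = NULL, excluded = TRUE,
                reason = "EEG epoch rejected (amplitude threshold)",
                quality = list(bad_channels = eeg$bad_channels)))
  }
  # alpha-band reconstruction at 128 Hz, per channel (bad channels -> NA)
  alpha128 <- sapply(colnames(eeg$channels), function(ch) {
    x <- eeg$channels[, ch]
    if (anyNA(x)) rep(NA_real_, floor(duration * 128)) else {
      a <- alpha_band_signal(x, eeg$fs)
      length(a) <- floor(duration * 128)
      a
    }
  })
  nnr <- ecg_to_nn(trial$ecg, trial$ecg_fs)
  nn_times <- cumsum(nnr$nn) / 1000
  g <- preprocess_gsr(trial$gsr, trial$gsr_fs, stats = gsr_stats)

  wins <- feature_windows(duration, window_s, hop_s)
  seqm <- t(vapply(seq_len(nrow(wins)), function(i) {
    window_features(alpha128, nnr$nn, nn_times, g$z, g$fs, g$sd,
                    wins$start[i], wins$end[i])
  }, numeric(length(FEATURE_NAMES))))
  colnames(seqm) <- FEATURE_NAMES
  tl <- window_features(alpha128, nnr$nn, nn_times, g$z, g$fs, g$sd,
                        0, duration)
  list(trial = tl, seq = seqm, excluded = FALSE, reason = NA_character_,
       quality = list(n_corrected = nnr$n_corrected,
                      bad_channels = eeg$bad_channels,
                      low_quality_nn = nnr$low_quality))
}

#' Extract feature tables for a whole synthetic experiment
#'
#' Streams trial generation participant by participant (so that GSR
#' normalization constants are pooled over each participant's full
#' recording set, label-blind) and assembles the trial-level and windowed
#' feature tables.
#'
#' @param config a [synth_config()].
#' @param window_s,hop_s sequence windowing (s).
#' @param verbose print per-participant progress.
#' @return list: `trial_table` and `window_table` (data.frames with
#'   columns participant, trial, label, window_index and the 11 features;
#'   `window_index` is -1 in the trial-level table), `exclusions`
#'   (data.frame of excluded trials and reasons).
#' @export
extract_features_experiment <- function(config, window_s = 60, hop_s = 20,
                                        verbose = FALSE) {
  mf <- experiment_manifest(config)
  trial_rows <- list(); win_rows <- list(); excl <- list()
  for (pid in seq_len(config$n_participants)) {
    sub <- mf[mf$participant == pid, ]
    trials <- lapply(seq_len(nrow(sub)), function(i) {
      simulate_trial(config, pid, sub$label[i], sub$rep[i], sub$trial[i])
    })
    gstats <- participant_gsr_stats(
      lapply(trials, function(tr) gsr_lowpass(tr$gsr, tr$gsr_fs)$signal))
    for (i in seq_along(trials)) {
      fx <- extract_features(trials[[i]], gsr_stats = gstats,
                             window_s = window_s, hop_s = hop_s)
      meta <- data.frame(participant = pid, trial = sub$trial[i],
                         label = sub$label[i])
      if (fx$excluded) {
        excl[[length(excl) + 1]] <- cbind(meta, reason = fx$reason)
        next
      }
      trial_rows[[length(trial_rows) + 1]] <-
        cbind(meta, window_index = -1L, as.data.frame(t(fx$trial)))
      win_rows[[length(win_rows) + 1]] <-
        cbind(meta[rep(1, nrow(fx$seq)), ],
              window_index = seq_len(nrow(fx$seq)) - 1L,
              as.data.frame(fx$seq))
    }
    if (verbose) message("participant ", pid, "/", config$n_participants)
  }
  list(trial_table = do.call(rbind, trial_rows),
       window_table = do.call(rbind, win_rows),
       exclusions = if (length(excl)) do.call(rbind, excl) else
         data.frame(participant = integer(0), trial = integer(0),
                    label = character(0), reason = character(0)))
}
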