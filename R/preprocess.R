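# Modality-specific preprocessing: EEG referencing/filtering/rejection,
# ECG R-peak detection and NN-series construction, GSR filtering and
# within-participant normalization.

#' Preprocess a six-channel EEG epoch
#'
#' Applies, per channel, a 50 Hz notch (Q = 30) and the 0.05-100 Hz
#' acquisition band re-applied digitally (cascaded order-2 high- and
#' low-pass Butterworth sections, zero-phase); channels whose SD exceeds
#' five times the median channel SD are marked bad and excluded from the
#' average reference; the epoch is flagged rejected if any retained sample
#' exceeds +/-100 uV after cleaning.
#'
#' @param raw samples x 6 numeric matrix, channels FP1, FP2, F3, F4, F7, F8
#'   (microvolts).
#' @param fs sampling rate (Hz), >= 256.
#' @param reject_uv rejection threshold (microvolts).
#' @return list: `channels` (cleaned, average-referenced matrix; bad
#'   channels are all-NA), `rejected` flag, `bad_channels`, `fs`.
#' @export
preprocess_eeg <- function(raw, fs, reject_uv = 100) {
  if (is.null(dim(raw)) || ncol(raw) != 6) {
    stop("EEG input must have exactly 6 channels")
  }
  stopifnot(fs >= 256)
  if (is.null(colnames(raw))) colnames(raw) <- EEG_CHANNELS
  filt <- apply(raw, 2, function(ch) {
    ch <- notch_filter(ch, fs, freq = 50, Q = 30)
    ch <- butter_filtfilt(ch, fs, "high", 0.05, order = 2)
    butter_filtfilt(ch, fs, "low", min(100, 0.45 * fs), order = 2)
  })
  sds <- apply(filt, 2, stats::sd)
  bad <- sds > 5 * stats::median(sds)
  if (all(bad)) {
    return(list(channels = filt * NA, rejected = TRUE,
                bad_channels = colnames(raw), fs = fs))
  }
  ref <- rowMeans(filt[, !bad, drop = FALSE])
  out <- filt - ref
  out[, bad] <- NA_real_
  rejected <- any(abs(out[, !bad, drop = FALSE]) > reject_uv)
  list(channels = out, rejected = rejected,
       bad_channels = colnames(raw)[bad], fs = fs)
}

#' Pan-Tompkins R-peak detection
#'
#' Classic stage sequence: 5-15 Hz bandpass, five-point derivative,
#' squaring, 150 ms moving-window integration, adaptive dual thresholds
#' with search-back, 200 ms refractory period. Detected peaks are relocated
#' to the local ECG maximum within +/-50 ms.
#'
#' @param ecg numeric ECG signal (mV), >= 5 s.
#' @param fs sampling rate (Hz), >= 200.
#' @return list: `peaks` (strictly increasing sample indices), `fs`.
#' @export
detect_r_peaks <- function(ecg, fs) {
  stopifnot(fs >= 200)
  n <- length(ecg)
  if (n < 5 * fs) stop("need at least 5 s of ECG")
  bp <- butter_filtfilt(ecg, fs, "pass", c(5, 15), order = 2)
  # five-point derivative
  d <- stats::filter(bp, c(2, 1, 0, -1, -2) / 8, sides = 2)
  d[is.na(d)] <- 0
  sq <- as.numeric(d)^2
  w <- max(3L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) {
    warning("no R peaks found")
    return(list(peaks = integer(0), fs = fs))
  }
  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- 0.5 * max(init)
  npki <- 0.5 * mean(init)
  refr <- round(0.2 * fs)
  qrs <- integer(0)
  rr_hist <- numeric(0)
  noise_cand <- integer(0)
  for (p in cand) {
    thr <- npki + 0.25 * (spki - npki)
    if (length(qrs) && (p - qrs[length(qrs)]) < refr) {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      next
    }
    # search-back: expected beat missed
    if (length(rr_hist) >= 2 && length(qrs)) {
      rr_avg <- mean(utils::tail(rr_hist, 8))
      if ((p - qrs[length(qrs)]) > 1.66 * rr_avg && length(noise_cand)) {
        sb <- noise_cand[noise_cand > qrs[length(qrs)] + refr & noise_cand < p]
        sb <- sb[mwi[sb] > 0.5 * thr]
        if (length(sb)) {
          best <- sb[which.max(mwi[sb])]
          spki <- 0.25 * mwi[best] + 0.75 * spki
          if (length(qrs)) rr_hist <- c(rr_hist, best - qrs[length(qrs)])
          qrs <- c(qrs, best)
          noise_cand <- integer(0)
        }
      }
    }
    if (mwi[p] > thr) {
      if (length(qrs)) rr_hist <- c(rr_hist, p - qrs[length(qrs)])
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      noise_cand <- integer(0)
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      noise_cand <- c(noise_cand, p)
    }
  }
  if (!length(qrs)) {
    warning("no R peaks found")
    return(list(peaks = integer(0), fs = fs))
  }
  # The integrated signal peaks on a plateau (window minus QRS width), so
  # first refine each fiducial to the sharp maximum of the squared
  # derivative, then relocate to the local raw-ECG maximum within +/-50 ms.
  half_sq <- round(0.08 * fs)
  half <- round(0.05 * fs)
  peaks <- vapply(qrs, function(p) {
    lo <- max(1L, p - half_sq); hi <- min(n, p + half_sq)
    p2 <- lo + which.max(sq[lo:hi]) - 1L
    lo <- max(1L, p2 - half); hi <- min(n, p2 + half)
    as.integer(lo + which.max(ecg[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce the refractory period after relocation
  keep <- c(TRUE, diff(peaks) >= refr)
  list(peaks = peaks[keep], fs = fs)
}

#' Correct ectopic RR intervals (20% rule)
#'
#' A single left-to-right pass flags every interval deviating by more than
#' 20% from the last accepted (already corrected) interval; flagged runs
#' are replaced by linear interpolation between the nearest accepted
#' neighbours (constant extrapolation at either end). The reference is
#' initialized as the median of the first five intervals, so an ectopic
#' first interval cannot poison the whole pass.
#'
#' @param rr numeric RR intervals (ms), length >= 3.
#' @return list: `nn` (corrected normal-to-normal intervals, ms),
#'   `n_corrected`, `flagged` (logical), `low_quality` (TRUE when more than
#'   20% of beats were flagged).
#' @export
correct_ectopics <- function(rr) {
  stopifnot(length(rr) >= 3, all(rr > 0))
  n <- length(rr)
  flagged <- logical(n)
  last_ok <- stats::median(rr[seq_len(min(5, n))])
  for (i in 1:n) {
    if (abs(rr[i] - last_ok) / last_ok > 0.20) {
      flagged[i] <- TRUE
    } else {
      last_ok <- rr[i]
    }
  }
  nn <- rr
  if (all(flagged)) {
    nn[] <- last_ok
  } else if (any(flagged)) {
    runs <- rle(flagged)
    pos <- cumsum(c(1, runs$lengths))
    for (j in seq_along(runs$values)) {
      if (!runs$values[j]) next
      a <- pos[j] - 1          # last accepted before run; 0 if run starts at 1
      b <- pos[j + 1]          # first accepted after run, may exceed n
      len <- runs$lengths[j]
      if (a == 0) {
        nn[seq_len(len)] <- nn[b]
      } else if (b > n) {
        nn[a + seq_len(len)] <- nn[a]
      } else {
        nn[a + seq_len(len)] <- nn[a] +
          (nn[b] - nn[a]) * seq_len(len) / (len + 1)
      }
    }
  }
  lq <- mean(flagged) > 0.20
  if (lq) warning("more than 20% of beats flagged as ectopic: low-quality trial")
  list(nn = nn, n_corrected = sum(flagged), flagged = flagged,
       low_quality = lq)
}

#' NN series from a raw ECG trial
#'
#' Convenience wrapper: Pan-Tompkins detection (after the 0.5-35 Hz
#' acquisition band re-applied digitally), RR construction, ectopic
#' correction.
#'
#' @param ecg numeric ECG (mV).
#' @param fs sampling rate (Hz).
#' @return list as [correct_ectopics()] plus `peaks` and `beat_times_s`.
#' @export
ecg_to_nn <- function(ecg, fs) {
  ecg_f <- butter_filtfilt(ecg, fs, "pass", c(0.5, 35), order = 2)
  det <- detect_r_peaks(ecg_f, fs)
  if (length(det$peaks) < 4) stop("too few R peaks detected")
  rr <- diff(det$peaks) / fs * 1000
  out <- correct_ectopics(rr)
  out$peaks <- det$peaks
  out$beat_times_s <- det$peaks[-1] / fs
  out
}

#' Low-pass filter a skin conductance signal
#'
#' Anti-aliased decimation to 25 Hz (when the input rate is a multiple of
#' 25 above 100 Hz) followed by an order-4 zero-phase Butterworth low-pass
#' at 0.3 Hz.
#'
#' @param raw numeric GSR signal (microsiemens).
#' @param fs sampling rate (Hz), >= 4.
#' @return list: `signal` (filtered, microsiemens), `fs` (output rate).
#' @export
gsr_lowpass <- function(raw, fs) {
  stopifnot(fs >= 4)
  if (fs >= 100 && fs %% 25 == 0) {
    raw <- decimate_by(raw, fs / 25)
    fs <- 25
  }
  list(signal = butter_filtfilt(raw, fs, "low", 0.3, order = 4), fs = fs)
}

#' Pooled normalization constants for a participant's GSR recordings
#'
#' @param signals list of filtered GSR signals (output of [gsr_lowpass()]),
#'   all trials of one participant, label-blind.
#' @return list: `mean`, `sd` (microsiemens).
#' @export
participant_gsr_stats <- function(signals) {
  x <- unlist(signals, use.names = FALSE)
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) stop("zero-variance GSR recording")
  list(mean = m, sd = s)
}

#' Preprocess a skin conductance trial
#'
#' Low-pass filtering (see [gsr_lowpass()]) followed by Z-score
#' normalization using the participant's pooled constants; when no
#' constants are supplied the trial's own mean/SD are used.
#'
#' @param raw numeric GSR (microsiemens).
#' @param fs sampling rate (Hz).
#' @param stats optional list with `mean` and `sd` from
#'   [participant_gsr_stats()].
#' @return list: `z` (normalized samples), `fs`, `mean`, `sd` (the raw-unit
#'   normalization constants, needed to apply amplitude thresholds stated
#'   in microsiemens).
#' @export
preprocess_gsr <- function(raw, fs, stats = NULL) {
  lp <- gsr_lowpass(raw, fs)
  if (is.null(stats)) stats <- participant_gsr_stats(list(lp$signal))
  if (!is.finite(stats$sd) || stats$sd < 1e-12) stop("zero-variance GSR recording")
  list(z = (lp$signal - stats$mean) / stats$sd, fs = lp$fs,
       mean = stats$mean, sd = stats$sd)
}
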