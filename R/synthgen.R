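# Synthetic multimodal trial generator.
#
# Emulates the emotion-conditioned statistical structure of a VR emotion
# study: class-dependent prefrontal alpha asymmetry (positive > neutral >
# negative), class-dependent heart-rate variability (reduced SDNN/RMSSD and
# sample entropy, elevated LF/HF under negative emotion), class-dependent
# electrodermal activity (highest SCL and SCR rate under negative emotion)
# and SAM self-ratings drawn from the pooled per-category distributions of
# the stimulus-validation table. All injected events (R peaks, SCR onsets,
# asymmetry offsets) are returned as ground truth.

#' Emotion-conditioned generator profile
#'
#' Bundles the class-conditional parameters used by the synthetic trial
#' generator.
#'
#' @param label one of "positive", "neutral", "negative".
#' @param alpha_asym_shift named length-3 numeric: mean asymmetry-index
#'   offset (ln-power units) for the Fp2/Fp1, F4/F3 and F8/F7 pairs.
#' @param rr_mean mean RR interval (ms), in \[400, 1500\].
#' @param rr_sdnn_target target SDNN of the RR series (ms).
#' @param lf_hf_target target ratio of LF to HF oscillatory power.
#' @param sampen_target nominal sample-entropy level; steers the white
#'   jitter share of the RR variance partition (larger = more irregular).
#' @param scr_rate non-specific skin conductance responses per minute.
#' @param scl_level tonic skin conductance level (microsiemens).
#' @param sam_valence_mean,sam_valence_sd,sam_arousal_mean,sam_arousal_sd
#'   SAM rating distribution on the 1-9 scale.
#' @return an `emotion_profile` list.
#' @export
emotion_profile <- function(label,
                            alpha_asym_shift = c(Fp2Fp1 = 0, F4F3 = 0, F8F7 = 0),
                            rr_mean = 800, rr_sdnn_target = 50,
                            lf_hf_target = 1.5, sampen_target = 1.4,
                            scr_rate = 2, scl_level = 5,
                            sam_valence_mean = 5, sam_valence_sd = 0.5,
                            sam_arousal_mean = 5, sam_arousal_sd = 0.5) {
  label <- match.arg(label, c("positive", "neutral", "negative"))
  stopifnot(length(alpha_asym_shift) == 3,
            rr_mean >= 400, rr_mean <= 1500,
            rr_sdnn_target >= 0, lf_hf_target > 0, sampen_target > 0,
            scr_rate >= 0, scl_level > 0,
            sam_valence_mean >= 1, sam_valence_mean <= 9,
            sam_arousal_mean >= 1, sam_arousal_mean <= 9,
            sam_valence_sd >= 0, sam_arousal_sd >= 0)
  names(alpha_asym_shift) <- c("Fp2Fp1", "F4F3", "F8F7")
  structure(list(label = label, alpha_asym_shift = alpha_asym_shift,
                 rr_mean = rr_mean, rr_sdnn_target = rr_sdnn_target,
                 lf_hf_target = lf_hf_target, sampen_target = sampen_target,
                 scr_rate = scr_rate, scl_level = scl_level,
                 sam_valence_mean = sam_valence_mean,
                 sam_valence_sd = sam_valence_sd,
                 sam_arousal_mean = sam_arousal_mean,
                 sam_arousal_sd = sam_arousal_sd),
            class = "emotion_profile")
}

#' Published SAM rating table for the 18 stimulus videos
#'
#' Printed mean and SD of valence and arousal ratings for each selected VR
#' video, with its assigned emotion category.
#'
#' @return data.frame with one row per video.
#' @export
video_ratings <- function() {
  utils::read.delim(system.file("extdata", "video_ratings.tsv",
                                package = "emofuse"),
                    stringsAsFactors = FALSE)
}

# Pooled per-category SAM distribution: mean of video means, RMS-pooled SD.
pooled_sam <- function(ratings, category) {
  r <- ratings[ratings$category == category, ]
  list(valence_mean = mean(r$valence_mean),
       valence_sd = sqrt(mean(r$valence_sd^2)),
       arousal_mean = mean(r$arousal_mean),
       arousal_sd = sqrt(mean(r$arousal_sd^2)))
}

#' Default emotion profiles
#'
#' Class-conditional generator settings encoding the qualitative group
#' contrasts of the study: alpha asymmetry graded positive > neutral >
#' negative on the dorsolateral pairs (frontopolar pair near-null), reduced
#' SDNN/sample entropy and raised LF/HF under negative emotion, and highest
#' SCL/SCR rate under negative emotion. SAM parameters are the pooled
#' per-category values of [video_ratings()].
#'
#' @return named list of three [emotion_profile()] objects.
#' @export
default_profiles <- function() {
  rt <- video_ratings()
  sp <- pooled_sam(rt, "positive")
  sn <- pooled_sam(rt, "neutral")
  sg <- pooled_sam(rt, "negative")
  list(
    positive = emotion_profile("positive",
      alpha_asym_shift = c(Fp2Fp1 = 0, F4F3 = 0.45, F8F7 = 0.40),
      rr_mean = 820, rr_sdnn_target = 55, lf_hf_target = 1.5,
      sampen_target = 1.5, scr_rate = 3.5, scl_level = 5.8,
      sam_valence_mean = sp$valence_mean, sam_valence_sd = sp$valence_sd,
      sam_arousal_mean = sp$arousal_mean, sam_arousal_sd = sp$arousal_sd),
    neutral = emotion_profile("neutral",
      alpha_asym_shift = c(Fp2Fp1 = 0.00, F4F3 = 0.15, F8F7 = 0.12),
      rr_mean = 860, rr_sdnn_target = 50, lf_hf_target = 1.2,
      sampen_target = 1.4, scr_rate = 1.5, scl_level = 4.5,
      sam_valence_mean = sn$valence_mean, sam_valence_sd = sn$valence_sd,
      sam_arousal_mean = sn$arousal_mean, sam_arousal_sd = sn$arousal_sd),
    negative = emotion_profile("negative",
      alpha_asym_shift = c(Fp2Fp1 = 0, F4F3 = -0.30, F8F7 = -0.25),
      rr_mean = 760, rr_sdnn_target = 30, lf_hf_target = 4.0,
      sampen_target = 0.9, scr_rate = 7, scl_level = 7.5,
      sam_valence_mean = sg$valence_mean, sam_valence_sd = sg$valence_sd,
      sam_arousal_mean = sg$arousal_mean, sam_arousal_sd = sg$arousal_sd)
  )
}

#' Synthetic experiment configuration
#'
#' @param n_participants number of participants (default 20).
#' @param trials_per_class number of trials per emotion class per
#'   participant (default 6).
#' @param eeg_fs,ecg_fs,gsr_fs sampling rates in Hz (defaults 512/500/500).
#' @param trial_duration trial length in seconds (default 120).
#' @param profiles named list of three [emotion_profile()] objects.
#' @param artifact_rates list: `blinks_per_min` (ocular transients on
#'   Fp1/Fp2; default 0 so that default trials emulate the post-artifact-
#'   removal state and survive amplitude-threshold rejection),
#'   `ectopic_prob` (per-beat probability of an RR perturbation violating
#'   the 20% rule), `powerline_uv` (50 Hz common-mode amplitude),
#'   `ecg_noise_mv`, `gsr_noise_us` (additive Gaussian noise).
#' @param variability list of between-participant and trial-to-trial
#'   dispersion parameters (see the methods vignette).
#' @param seed integer RNG seed; the whole experiment is a pure function of
#'   the configuration.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_participants = 20, trials_per_class = 6,
                         eeg_fs = 512, ecg_fs = 500, gsr_fs = 500,
                         trial_duration = 120,
                         profiles = default_profiles(),
                         artifact_rates = list(),
                         variability = list(),
                         seed = 20260415L) {
  if (n_participants < 1 || trials_per_class < 1 || trial_duration <= 0) {
    stop("n_participants, trials_per_class and trial_duration must be positive")
  }
  stopifnot(eeg_fs >= 128, ecg_fs >= 200, gsr_fs >= 4)
  ar <- utils::modifyList(list(blinks_per_min = 0, ectopic_prob = 0.02,
                               powerline_uv = 5, ecg_noise_mv = 0.03,
                               gsr_noise_us = 0.005), artifact_rates)
  vb <- utils::modifyList(list(
    ai_participant_sd = 0.12,  # stable individual asymmetry baseline
    ai_trial_sd = 0.35,        # trial-to-trial asymmetry fluctuation
    rr_participant_sd = 50,    # ms, resting-rate differences
    hrv_participant_cv = 0.12, # lognormal CV of SDNN scale per participant
    hrv_trial_cv = 0.25,       # lognormal CV of SDNN target per trial
    lfhf_trial_cv = 0.50,      # lognormal CV of the LF/HF target per trial
    scl_participant_sd = 0.8,  # microsiemens
    scl_trial_sd = 1.2,
    scr_rate_trial_cv = 0.60,
    alpha_rms_uv = 6,          # baseline alpha-band RMS amplitude
    pink_rms_uv = 3            # broadband 1/f background RMS
  ), variability)
  stopifnot(all(vapply(profiles, inherits, logical(1), "emotion_profile")))
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_class = as.integer(trials_per_class),
                 eeg_fs = eeg_fs, ecg_fs = ecg_fs, gsr_fs = gsr_fs,
                 trial_duration = trial_duration, profiles = profiles,
                 artifact_rates = ar, variability = vb,
                 seed = as.integer(seed)),
            class = "synth_config")
}

EEG_CHANNELS <- c("FP1", "FP2", "F3", "F4", "F7", "F8")

# 1/f ("pink") noise via spectral shaping, unit RMS.
pink_noise <- function(n) {
  nf <- floor(n / 2)
  f <- seq_len(nf)
  mag <- 1 / sqrt(f)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- complex(length.out = n)
  full[2:(nf + 1)] <- spec
  full[n:(n - nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

# Narrowband alpha oscillation (8-13 Hz filtered white noise), unit RMS.
alpha_oscillation <- function(n, fs) {
  x <- butter_filtfilt(stats::rnorm(n + 2 * fs), fs, "pass", c(8, 13), order = 4)
  x <- x[(fs + 1):(fs + n)]
  x / stats::sd(x)
}

#' Generate one six-channel prefrontal EEG trial
#'
#' Each channel is a 1/f background plus an alpha-band (8-13 Hz)
#' oscillation whose right/left power ratio per homologous pair equals
#' `exp(shift)` by construction; optional ocular transients (100-400 uV)
#' are injected on Fp1/Fp2 and a 50 Hz common-mode component on all
#' channels.
#'
#' @param profile an [emotion_profile()].
#' @param duration trial length (s).
#' @param fs sampling rate (Hz), >= 128.
#' @param artifact_rates,variability see [synth_config()].
#' @param ai_offsets optional length-3 numeric: per-pair asymmetry offset
#'   added to the profile shift (participant/trial effects). Default 0.
#' @return list with `signals` (samples x 6 matrix, channels named) and
#'   `ai_true` (realized per-pair asymmetry, ln-power units).
#' @export
generate_eeg <- function(profile, duration, fs,
                         artifact_rates = synth_config()$artifact_rates,
                         variability = synth_config()$variability,
                         ai_offsets = c(0, 0, 0)) {
  stopifnot(fs >= 128)
  n <- round(duration * fs)
  ai <- profile$alpha_asym_shift + ai_offsets
  p0 <- variability$alpha_rms_uv^2
  sig <- matrix(0, n, 6, dimnames = list(NULL, EEG_CHANNELS))
  pairs <- list(c("FP1", "FP2"), c("F3", "F4"), c("F7", "F8"))
  for (k in 1:3) {
    p_left <- p0 * exp(-ai[k] / 2)
    p_right <- p0 * exp(ai[k] / 2)
    sig[, pairs[[k]][1]] <- sqrt(p_left) * alpha_oscillation(n, fs)
    sig[, pairs[[k]][2]] <- sqrt(p_right) * alpha_oscillation(n, fs)
  }
  for (ch in 1:6) sig[, ch] <- sig[, ch] + variability$pink_rms_uv * pink_noise(n)
  if (artifact_rates$powerline_uv > 0) {
    pl <- artifact_rates$powerline_uv * sin(2 * pi * 50 * seq_len(n) / fs)
    sig <- sig + pl  # common mode on every channel
  }
  if (artifact_rates$blinks_per_min > 0) {
    n_blinks <- stats::rpois(1, artifact_rates$blinks_per_min * duration / 60)
    if (n_blinks > 0) {
      centers <- stats::runif(n_blinks, 1, duration - 1)
      amps <- stats::runif(n_blinks, 100, 400)
      tt <- seq_len(n) / fs
      for (b in seq_len(n_blinks)) {
        pulse <- amps[b] * exp(-0.5 * ((tt - centers[b]) / 0.08)^2)
        sig[, "FP1"] <- sig[, "FP1"] + pulse
        sig[, "FP2"] <- sig[, "FP2"] + pulse
      }
    }
  }
  list(signals = sig, ai_true = stats::setNames(as.numeric(ai),
                                                c("Fp2Fp1", "F4F3", "F8F7")))
}

#' Generate an RR-interval series with controlled HRV structure
#'
#' RR(t) = mean + LF oscillation (0.1 Hz) + HF oscillation (0.25 Hz) +
#' white jitter. Oscillation amplitudes and jitter variance partition the
#' target SDNN so that sample SDNN and the extracted LF/HF ratio match the
#' profile targets in expectation; the white-jitter share is a monotone
#' function of `sampen_target` (more jitter, higher entropy). Ectopic beats
#' (RR multiplied by 0.6 or 1.5, guaranteeing a >20% deviation) are
#' injected with the configured per-beat probability.
#'
#' @param profile an [emotion_profile()].
#' @param duration recording length (s).
#' @param ectopic_prob per-beat ectopic probability.
#' @param sdnn_scale,lfhf_scale multiplicative adjustments of the profile
#'   targets (participant/trial effects); default 1.
#' @param rr_mean_offset additive offset on the mean RR (ms); default 0.
#' @return list: `rr_ms` (intervals), `beat_times_s` (cumulative beat
#'   times, first beat at rr_1), `ectopic` (logical per beat).
#' @export
generate_rr_series <- function(profile, duration,
                               ectopic_prob = 0,
                               sdnn_scale = 1, lfhf_scale = 1,
                               rr_mean_offset = 0) {
  rr_mean <- profile$rr_mean + rr_mean_offset
  stopifnot(rr_mean >= 400, rr_mean <= 1500)
  sdnn <- profile$rr_sdnn_target * sdnn_scale
  r <- profile$lf_hf_target * lfhf_scale
  # White-jitter variance share from the entropy target (heuristic
  # monotone map, clamped to keep the partition feasible).
  phi <- min(0.85, max(0.02, 0.3 * profile$sampen_target - 0.15))
  if (sdnn < 0 || phi >= 1) stop("infeasible RR variance partition")
  var_total <- sdnn^2
  var_jitter <- phi * var_total
  var_osc <- (1 - phi) * var_total
  # Beat-sampled white jitter spreads its variance over 0..beat_rate/2 Hz,
  # contributing to both HRV bands; the tone powers are solved so that the
  # extracted LF/HF band-power ratio matches the target.
  half_br <- (1000 / rr_mean) / 2
  j_lf <- var_jitter * 0.11 / half_br
  j_hf <- var_jitter * 0.25 / half_br
  p_lf <- min(var_osc, max(0, (r * (var_osc + j_hf) - j_lf) / (1 + r)))
  p_hf <- var_osc - p_lf
  a_lf <- sqrt(2 * p_lf)
  a_hf <- sqrt(2 * p_hf)
  s_j <- sqrt(var_jitter)
  if (sdnn == 0) a_lf <- a_hf <- s_j <- 0
  ph_lf <- stats::runif(1, 0, 2 * pi)
  ph_hf <- stats::runif(1, 0, 2 * pi)
  rr <- numeric(0); times <- numeric(0); ect <- logical(0)
  t <- 0
  repeat {
    rk <- rr_mean + a_lf * sin(2 * pi * 0.1 * t + ph_lf) +
      a_hf * sin(2 * pi * 0.25 * t + ph_hf) +
      if (s_j > 0) stats::rnorm(1, 0, s_j) else 0
    is_ect <- ectopic_prob > 0 && stats::runif(1) < ectopic_prob
    if (is_ect) rk <- rk * sample(c(0.6, 1.5), 1)
    rk <- max(rk, 320)  # physiological floor
    if (t + rk / 1000 > duration + 1e-9) break
    t <- t + rk / 1000
    rr <- c(rr, rk); times <- c(times, t); ect <- c(ect, is_ect)
  }
  list(rr_ms = rr, beat_times_s = times, ectopic = ect)
}

# PQRST template: sum of Gaussian deflections relative to the R peak (s).
ecg_template <- function(t_rel) {
  0.12 * exp(-0.5 * ((t_rel + 0.20) / 0.025)^2) -
  0.15 * exp(-0.5 * ((t_rel + 0.025) / 0.008)^2) +
  1.00 * exp(-0.5 * (t_rel / 0.012)^2) -
  0.25 * exp(-0.5 * ((t_rel - 0.030) / 0.010)^2) +
  0.30 * exp(-0.5 * ((t_rel - 0.300) / 0.060)^2)
}

#' Synthesize an ECG signal from beat times
#'
#' Places a template PQRST complex (R amplitude ~1 mV) at every beat time
#' and adds Gaussian measurement noise.
#'
#' @param beat_times_s strictly increasing beat times (s).
#' @param fs sampling rate (Hz).
#' @param duration signal length (s).
#' @param noise_sd Gaussian noise SD (mV).
#' @return list: `signal` (mV) and `r_peaks` (ground-truth sample indices).
#' @export
generate_ecg_from_rr <- function(beat_times_s, fs, duration,
                                 noise_sd = 0) {
  n <- round(duration * fs)
  x <- numeric(n)
  if (length(beat_times_s) > 0) {
    if (any(diff(beat_times_s) <= 0)) stop("beat times must be strictly increasing")
    if (any(diff(beat_times_s) < 0.3)) stop("RR below 300 ms: overlapping complexes")
    tt <- seq_len(n) / fs
    for (bt in beat_times_s) {
      lo <- max(1L, floor((bt - 0.45) * fs)); hi <- min(n, ceiling((bt + 0.55) * fs))
      idx <- lo:hi
      x[idx] <- x[idx] + ecg_template(tt[idx] - bt)
    }
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  r_idx <- pmin(round(beat_times_s * fs), length(x))
  list(signal = x, r_peaks = as.integer(r_idx[r_idx >= 1]))
}

# Biexponential SCR kernel (rise ~1 s time constant, decay ~4 s),
# normalized to unit peak.
scr_kernel <- function(t, tau_rise = 1, tau_decay = 4) {
  k <- exp(-t / tau_decay) - exp(-t / tau_rise)
  t_peak <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  k / (exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise))
}

#' Deterministic skin conductance signal from known SCR events
#'
#' Builds a conductance signal with biexponential responses at exactly the
#' given onsets/amplitudes on a constant tonic level (no drift, no noise);
#' the ground-truth injection primitive behind [generate_gsr()].
#'
#' @param onsets_s SCR onset times (s).
#' @param amplitudes peak amplitudes (microsiemens), same length.
#' @param duration signal length (s).
#' @param fs sampling rate (Hz).
#' @param scl_level constant tonic level (microsiemens).
#' @return numeric signal.
#' @export
gsr_from_events <- function(onsets_s, amplitudes, duration, fs,
                            scl_level = 0) {
  n <- round(duration * fs)
  x <- rep(scl_level, n)
  tt <- seq_len(n) / fs
  for (i in seq_along(onsets_s)) {
    idx <- which(tt >= onsets_s[i] & tt <= onsets_s[i] + 25)
    if (length(idx)) x[idx] <- x[idx] + amplitudes[i] * scr_kernel(tt[idx] - onsets_s[i])
  }
  x
}

#' Generate a skin conductance trial
#'
#' Tonic level plus slow drift, with phasic skin conductance responses
#' drawn as a minimum-gap (7 s) thinned Poisson process with biexponential
#' kernels. The minimum inter-onset gap keeps every injected event
#' individually resolvable by trough-to-peak detection, so the realized
#' event rate is a thinned version of `scr_rate`.
#'
#' @param profile an [emotion_profile()].
#' @param duration length (s).
#' @param fs sampling rate (Hz).
#' @param noise_sd additive Gaussian noise (microsiemens).
#' @param scl_offset additive tonic offset (participant/trial effects).
#' @param rate_scale multiplicative SCR-rate adjustment.
#' @return list: `signal` (microsiemens), `scr_onsets_s`,
#'   `scr_amplitudes`.
#' @export
generate_gsr <- function(profile, duration, fs, noise_sd = 0,
                         scl_offset = 0, rate_scale = 1) {
  stopifnot(profile$scr_rate >= 0)
  n <- round(duration * fs)
  tt <- seq_len(n) / fs
  scl <- profile$scl_level + scl_offset
  # slow enough that no 5 s drift rise can reach the 0.01 uS SCR threshold
  drift <- 0.2 * sin(2 * pi * tt / 160 + stats::runif(1, 0, 2 * pi)) +
    0.05 * (tt - duration / 2) / duration
  onsets <- numeric(0)
  rate <- profile$scr_rate * rate_scale / 60  # events per second
  if (rate > 0) {
    t <- stats::rexp(1, rate)
    while (t < duration - 8) {  # leave room for the rise to complete
      onsets <- c(onsets, t)
      t <- t + 7 + stats::rexp(1, rate)  # 7 s refractory gap
    }
  }
  amps <- if (length(onsets)) {
    pmin(0.8, pmax(0.1, stats::rlnorm(length(onsets), log(0.25), 0.35)))
  } else numeric(0)
  x <- gsr_from_events(onsets, amps, duration, fs, scl_level = scl) + drift
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  list(signal = x, scr_onsets_s = onsets, scr_amplitudes = amps)
}

#' Draw SAM self-ratings from a profile
#'
#' Gaussian draws at the profile means/SDs, clipped to the 1-9 scale.
#'
#' @param profile an [emotion_profile()].
#' @param n number of (valence, arousal) pairs.
#' @return data.frame with columns `valence`, `arousal`.
#' @export
generate_sam_ratings <- function(profile, n = 1) {
  v <- pmin(9, pmax(1, stats::rnorm(n, profile$sam_valence_mean,
                                    profile$sam_valence_sd)))
  a <- pmin(9, pmax(1, stats::rnorm(n, profile$sam_arousal_mean,
                                    profile$sam_arousal_sd)))
  data.frame(valence = v, arousal = a)
}

# Stable per-participant random effects (same across the participant's
# trials), drawn from a dedicated deterministic stream.
participant_effects <- function(config, pid) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 77L, pid))
  vb <- config$variability
  list(ai_offset = stats::rnorm(3, 0, vb$ai_participant_sd),
       rr_offset = stats::rnorm(1, 0, vb$rr_participant_sd),
       hrv_scale = stats::rlnorm(1, 0, vb$hrv_participant_cv),
       scl_offset = stats::rnorm(1, 0, vb$scl_participant_sd))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Trial plan of a synthetic experiment
#'
#' The design manifest: one row per trial, perfectly balanced across the
#' three emotion classes within every participant, with a seeded random
#' presentation order per participant.
#'
#' @param config a [synth_config()].
#' @return data.frame: `participant`, `trial`, `label`, `rep`.
#' @export
experiment_manifest <- function(config) {
  classes <- c("positive", "neutral", "negative")
  rows <- list()
  tid <- 0L
  for (pid in seq_len(config$n_participants)) {
    plan <- expand.grid(label = classes, rep = seq_len(config$trials_per_class),
                        stringsAsFactors = FALSE)
    old <- .Random.seed_save()
    set.seed(derive_seed(config$seed, 11L, pid))
    ord <- sample.int(nrow(plan))
    .Random.seed_restore(old)
    plan <- plan[ord, ]
    plan$participant <- pid
    plan$trial <- tid + seq_len(nrow(plan))
    tid <- tid + nrow(plan)
    rows[[pid]] <- plan
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("participant", "trial", "label", "rep")]
}

#' Simulate a single trial
#'
#' Deterministic given the configuration seed, participant, label and
#' repetition index; participant-level random effects are shared across a
#' participant's trials.
#'
#' @param config a [synth_config()].
#' @param pid participant index.
#' @param label emotion class.
#' @param rep repetition index within class.
#' @param trial_id global trial identifier to record.
#' @return a `trial_record` list: signals per modality, label, SAM
#'   ratings and ground truth (R-peak indices, SCR onsets, true asymmetry
#'   offsets, RR series, ectopic flags).
#' @export
simulate_trial <- function(config, pid, label, rep, trial_id = NA_integer_) {
  profile <- config$profiles[[label]]
  pe <- participant_effects(config, pid)
  vb <- config$variability
  ar <- config$artifact_rates
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 101L, pid,
                       match(label, c("positive", "neutral", "negative")), rep))
  dur <- config$trial_duration

  ai_trial <- stats::rnorm(3, 0, vb$ai_trial_sd)
  eeg <- generate_eeg(profile, dur, config$eeg_fs,
                      artifact_rates = ar, variability = vb,
                      ai_offsets = pe$ai_offset + ai_trial)

  sdnn_scale <- pe$hrv_scale * stats::rlnorm(1, 0, vb$hrv_trial_cv)
  lfhf_scale <- stats::rlnorm(1, 0, vb$lfhf_trial_cv)
  rr <- generate_rr_series(profile, dur, ectopic_prob = ar$ectopic_prob,
                           sdnn_scale = sdnn_scale, lfhf_scale = lfhf_scale,
                           rr_mean_offset = pe$rr_offset)
  ecg <- generate_ecg_from_rr(rr$beat_times_s, config$ecg_fs, dur,
                              noise_sd = ar$ecg_noise_mv)

  gsr <- generate_gsr(profile, dur, config$gsr_fs, noise_sd = ar$gsr_noise_us,
                      scl_offset = pe$scl_offset +
                        stats::rnorm(1, 0, vb$scl_trial_sd),
                      rate_scale = stats::rlnorm(1, 0, vb$scr_rate_trial_cv))

  sam <- generate_sam_ratings(profile, 1)
  structure(list(
    participant_id = pid, trial_id = trial_id, label = label, rep = rep,
    eeg = eeg$signals, ecg = ecg$signal, gsr = gsr$signal,
    eeg_fs = config$eeg_fs, ecg_fs = config$ecg_fs, gsr_fs = config$gsr_fs,
    sam_valence = sam$valence, sam_arousal = sam$arousal,
    ground_truth = list(r_peaks = ecg$r_peaks,
                        scr_onsets_s = gsr$scr_onsets_s,
                        scr_amplitudes = gsr$scr_amplitudes,
                        ai_true = eeg$ai_true,
                        rr_ms = rr$rr_ms, ectopic = rr$ectopic)),
    class = "trial_record")
}

#' Generate a full synthetic experiment
#'
#' @param config a [synth_config()].
#' @return list of `trial_record` objects (see [simulate_trial()]) with the
#'   design manifest attached as attribute `"manifest"`.
#' @export
generate_experiment <- function(config) {
  mf <- experiment_manifest(config)
  trials <- vector("list", nrow(mf))
  for (i in seq_len(nrow(mf))) {
    trials[[i]] <- simulate_trial(config, mf$participant[i],
                                  mf$label[i], mf$rep[i], mf$trial[i])
  }
  attr(trials, "manifest") <- mf
  trials
}
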