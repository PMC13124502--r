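---
title: "Multimodal physiological emotion recognition: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal physiological emotion recognition: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Emotional states modulate both the central and the autonomic nervous
system. Three well-established signatures are exploited here for
three-class emotion recognition (positive / neutral / negative):

* **Prefrontal alpha asymmetry.** Relatively greater right-hemisphere
  alpha-band (8–13 Hz) power over homologous frontal electrode pairs is
  associated with positive valence. The index is
  `AI = ln(P_alpha_right) − ln(P_alpha_left)` for the pairs Fp2/Fp1,
  F4/F3 and F8/F7.
* **Heart-rate variability (HRV).** Negative, high-arousal states show
  reduced beat-to-beat variability (SDNN, RMSSD), a shifted
  sympathovagal balance (higher LF/HF band-power ratio of the
  normal-to-normal interval tachogram) and reduced regulatory
  complexity (sample entropy).
* **Electrodermal activity.** Sympathetic arousal raises the tonic skin
  conductance level (SCL) and the rate of non-specific skin conductance
  responses (NS.SCRs).

The pipeline extracts these 11 features per 120-second trial, screens
them with a repeated-measures ANOVA inside each cross-validation fold,
fuses the surviving features at the feature level, reduces them with PCA
(90% cumulative variance) and classifies the resulting short feature
sequence with an LSTM, compared against four classical baselines under
nested stratified five-fold cross-validation.

Because no raw recordings of the motivating study are publicly
available, the package ships a synthetic-data generator whose defaults
encode the study's design (20 participants × 18 trials, 6 per class per
participant; EEG at 512 Hz on FP1/FP2/F3/F4/F7/F8; ECG and GSR at
500 Hz; 120 s per trial) and its qualitative class contrasts. Every
injected event — R-peak times, SCR onsets, per-pair asymmetry offsets —
is returned as ground truth, so each pipeline stage is testable against
what was actually put in.

# The synthetic generator

## Signal models

**EEG.** Each channel is 1/f ("pink") background noise (3 µV RMS)
plus an 8–13 Hz narrowband oscillation (filtered white noise, baseline
6 µV RMS). For a homologous pair with target asymmetry `s`, the left
and right alpha components are scaled to powers `P0·exp(∓s/2)`, so the
true power ratio is `exp(s)` by construction. A 50 Hz common-mode
sinusoid (5 µV) stands in for power-line pickup; ocular transients
(100–400 µV Gaussian pulses on Fp1/Fp2) can be injected at a configured
rate. The default blink rate is zero: the automated cleaning pipeline
replaces manual independent-component artifact removal with a ±100 µV
rejection rule, and any trial carrying a blink of that size would be
discarded rather than repaired. Default trials therefore emulate the
*post-artifact-removal* state of a recording; blink injection exists for
robustness tests of the rejection rule itself.

**ECG/RR.** The RR series is
`RR(t) = mean + a_LF·sin(2π·0.1·t) + a_HF·sin(2π·0.25·t) + ε`,
with `ε` white. The three amplitudes partition the squared SDNN target.
The white share is a monotone function of the profile's nominal sample
entropy (`phi = clamp(0.3·sampen_target − 0.15, 0.02, 0.85)`): more
broadband jitter produces a more irregular, higher-entropy series. The
LF/HF tone split accounts for the fact that beat-sampled white jitter
spreads its variance over 0–(beat rate/2) Hz and therefore leaks into
both spectral bands; the tone powers are solved so that the *extracted*
LF/HF band-power ratio matches the target in expectation. Ectopic beats
multiply RR by 0.6 or 1.5 with a configured per-beat probability, which
guarantees a violation of the 20% correction rule. The ECG trace places
a Gaussian-deflection PQRST template (R amplitude ≈ 1 mV) at each beat
time plus Gaussian sensor noise.

**GSR.** Tonic level plus a slow drift (0.2 µS sinusoid with a 160 s
period and a ±0.025 µS linear trend) plus phasic responses: a Poisson
process thinned to a minimum 7 s inter-onset gap, each event a
biexponential kernel (rise constant 1 s, decay 4 s) with amplitude drawn
from a clamped lognormal in [0.1, 0.8] µS. The gap and the drift rates
are chosen so that every injected event remains individually resolvable
after the 0.3 Hz low-pass: the zero-phase filter's symmetric ringing
creates small satellite bumps about 5 s around each sharp response, and
no 5-second stretch of pure drift can rise by the 0.01 µS detection
threshold. This is what makes the exact-count ground-truth tests
possible; it also means the realized event rate is a thinned version of
the nominal `scr_rate` (mean gap `7 + 1/λ` seconds).

**Ratings.** SAM valence/arousal are Gaussian draws clipped to [1, 9],
with per-category means and RMS-pooled SDs computed from the published
stimulus-validation table shipped in `inst/extdata/video_ratings.tsv`.

## Class profiles and calibration

Defaults (per class: F4/F3 and F8/F7 asymmetry shift, RR mean, SDNN
target, LF/HF target, entropy target, SCR rate, SCL):

| class | AI shift | RR (ms) | SDNN (ms) | LF/HF | SampEn | SCR/min | SCL (µS) |
|---|---|---|---|---|---|---|---|
| positive | +0.45 / +0.40 | 820 | 55 | 1.5 | 1.5 | 3.5 | 5.8 |
| neutral  | +0.15 / +0.12 | 860 | 50 | 1.2 | 1.4 | 1.5 | 4.5 |
| negative | −0.30 / −0.25 | 760 | 30 | 4.0 | 0.9 | 7.0 | 7.5 |

The frontopolar pair (Fp2/Fp1) carries no injected effect in any class:
in the motivating findings that index did not discriminate emotions, and
keeping it null gives the fold-wise screening a known negative.

Between-participant and trial-to-trial dispersion (stable participant
asymmetry offsets, resting-rate differences, lognormal HRV scale
factors, tonic conductance offsets; see `synth_config()`) are set so
that the classes are strongly but imperfectly separable: the nested
cross-validated accuracy of the full model at the default configuration
lands in the high-80s (%), with the permuted-label control at chance.
These dispersions are the generator's calibration — they are fixed once
in the defaults and shared by all tests and analyses.

## What the generator does and does not emulate

It emulates class-conditional *feature-level* structure with known
ground truth, participant heterogeneity, power-line pickup, sensor
noise, ectopic beats and (optionally) ocular artifacts. It does **not**
emulate biophysically realistic EEG sources, volume conduction,
movement artifacts of a head-mounted display, respiratory sinus
arrhythmia coupling, or the temporal evolution of an emotional episode
within a trial — the class-conditional parameters are constant across a
trial, so the windowed feature sequence differs across time only by
estimation noise. Passing tests therefore demonstrate the correctness
and leakage-freedom of the pipeline machinery under the assumed signal
models, not the field validity of the classifier on human recordings.

# Preprocessing

**EEG.** 50 Hz notch (biquad, Q = 30), then the 0.05–100 Hz acquisition
band re-applied digitally. The band-pass is realized as cascaded
order-2 high-pass and order-2 low-pass Butterworth sections because a
direct order-4 band-pass with a 0.05 Hz edge is numerically fragile in
transfer-function form. All filtering is zero-phase (forward–backward)
with odd-reflection edge padding sized to the filter's settling time;
the mean is filtered analytically (DC gain), so constant inputs pass
exactly and filtering is exactly affine-equivariant. Channels whose SD
exceeds 5× the median channel SD are marked bad and excluded from the
average reference; after referencing, a trial with any retained sample
beyond ±100 µV is rejected outright.

**ECG.** The 0.5–35 Hz acquisition band is re-applied, then a classic
Pan-Tompkins detector: 5–15 Hz band-pass, five-point derivative,
squaring, 150 ms moving-window integration, adaptive signal/noise
thresholds with search-back, 200 ms refractory period. Because the
integrated signal peaks on a plateau (window width minus QRS width),
each accepted fiducial is first refined to the sharp maximum of the
squared derivative (±80 ms) and then relocated to the local raw-ECG
maximum within ±50 ms. RR intervals deviating more than 20% from the
last accepted interval are flagged ectopic and linearly interpolated;
the reference is initialized as the median of the first five intervals
so that an ectopic *first* interval cannot poison the pass. Trials with
more than 20% flagged beats are marked low-quality.

**GSR.** Anti-aliased decimation to 25 Hz (an order-4 Butterworth at
0.3 Hz is well-conditioned there, and the passband is three decades
below the original Nyquist), zero-phase low-pass at 0.3 Hz, then
Z-scoring with mean/SD pooled over the participant's complete recording
set, label-blind. The raw-unit SD is kept so that amplitude thresholds
stated in microsiemens can be applied to the normalized signal.

# Feature extraction

* **Alpha power** by five-level db4 wavelet-packet decomposition of the
  128 Hz signal (periodic boundary; Gray-code node ordering). Terminal
  bands are 2 Hz wide, so the alpha band is covered by the 8–14 Hz
  nodes — the closest dyadic cover of 8–13 Hz. The three nodes are
  reconstructed, summed, and the power is the mean square of the
  reconstruction. db4 captures roughly 60–87% of a pure in-band tone
  (band-edge dependent) and < 5% out of band; the capture factor cancels
  exactly in the asymmetry log-ratio, which is why the asymmetry index
  recovers injected offsets within ±0.15 despite it.
* **HRV**: SDNN (n−1 denominator) and RMSSD over the windowed NN
  series; LF (0.04–0.15 Hz) and HF (0.15–0.40 Hz) band powers from a
  Welch periodogram (Hann, 64 s segments, 50% overlap) of the cubic
  spline 4 Hz resampled tachogram; sample entropy with the
  field-standard m = 2, r = 0.2·SD.
* **Electrodermal**: SCL is the window mean of the normalized signal;
  NS.SCRs are counted trough-to-peak on the low-passed signal — a local
  maximum qualifies when it rises ≥ 0.01 µS (raw units) above the
  minimum of the preceding 5 s and falls by at least half that within
  3 s; qualifying peaks closer than 5.5 s are merged (largest kept),
  which removes zero-phase filter ringing satellites. Distinct
  responses are in any case not resolvable below that scale after a
  0.3 Hz low-pass.

Features are computed over the full 120 s trial (for the group analyses
and screening) and over a 60 s window sliding by 20 s (4 steps), which
supplies the sequence axis for the LSTM. The window length is the
shortest span that still supports spectral HRV estimation down to the
LF band edge; the 20 s hop gives four steps per trial, enough for the
recurrence to integrate while keeping per-window estimates stable.

# Screening

One-way repeated-measures ANOVA per feature on participant × condition
means (trials averaged within participant and condition — consistent
with 2 and 38 degrees of freedom at 20 participants). The classical
within-subject partition is used; the Greenhouse–Geisser epsilon is
estimated from the sample covariance of the conditions, and selection
uses the corrected p-value at α = 0.05 (the conservative choice; both
p-values are reported). Under sphericity this makes the realized
selection rate of a null feature slightly conservative (≈ 4% at
α = 0.05, n = 20). Post-hoc pairwise contrasts use Tukey's HSD with the
omnibus error term. If fewer than two features pass in a fold, the
three smallest-p features are selected instead (logged) so that
downstream fusion always has an input; this fallback never triggers at
the default configuration. Participants with an empty condition cell in
a fold's training split are dropped from that fold's screening (logged).

# Dimensionality reduction and classification

Screened features are concatenated, standardized with training-fold
mean/SD (they have incommensurate units), and reduced by PCA: the
covariance of the pooled training *windows* is eigendecomposed and the
smallest k with ≥ 90% cumulative explained variance is retained.
Fitting PCA on windows and applying the same projection at every time
step preserves the sequence for the recurrent model while keeping a
single, well-determined projection per fold. Eigenvector signs are
fixed (largest-magnitude entry positive) for reproducibility.

The classifier is a single LSTM layer (96 hidden units) implemented
directly from the gate equations, followed by three fully connected
layers (128–64–32, rectified-linear) with dropout 0.4/0.3/0.2 and a
3-way softmax. Training: Adam (learning rate 0.001), minibatch 32, up
to 100 epochs, reduce-on-plateau (factor 0.5, patience 5) and early
stopping (patience 10) on the validation loss with best-validation
weights restored. Forget-gate biases are initialized at 1, other
weights Glorot-uniform. The seed controls initialization, dropout masks
and batch order, and training is exactly reproducible given the seed.
The implementation is plain matrix code with backpropagation through
time; its forward pass is verified against a unit-by-unit reference
implementation and its gradients against finite differences.

Baselines — SVM (RBF, C = 1, γ = 1/k), random forest (500 trees), kNN
(k = 5), XGBoost (300 rounds, depth 4, learning rate 0.1) — receive the
same fold-specific screened, standardized, PCA-reduced inputs with the
sequence axis collapsed by the mean (they are not sequence models).

# Evaluation

Outer stratified five-fold cross-validation at the trial level: each
fold's test block is untouched until evaluation; screening,
standardization, PCA and all model fitting happen strictly on the
training portion, from which a stratified 15% validation split is
carved for scheduling/early stopping. The effective split is therefore
68/12/20 — the closest five-fold realization of a 7:1.5:1.5 design.
Baselines are trained on the same 68% so all models see identical
inputs. Accuracy is aggregated over folds as mean ± SD (n−1). Paired
model comparisons use paired t-tests on fold-wise accuracies (df = 4),
95% t confidence intervals, Bonferroni correction over the four
comparisons against the reference model, and paired Cohen's d (mean
difference / SD of differences). A permuted-label control (labels
shuffled before any analysis, seeded) verifies that the pipeline has no
leakage path: its accuracy must be statistically indistinguishable from
chance. A sentinel test additionally corrupts every test-fold feature
value after the split and asserts the fold's screening tables, PCA
model and trained network weights are bit-identical.

Trial-level stratification matches the trial-wise design of the study;
a participant-grouped split would measure cross-person generalization,
a different (and harder) question that the motivating design did not
ask. This is the main caveat when reading the accuracy numbers.

# Numerical choices

* Zero-phase IIR filtering uses odd-reflection padding of
  `(1 + order/2)/f_c` seconds and analytic DC handling; without this,
  edge transients of the 0.3 Hz low-pass are large enough to create
  spurious electrodermal "responses" at the trial boundaries.
* The wavelet-packet transform uses periodic boundary handling, making
  the analysis/synthesis pair exactly orthogonal (perfect
  reconstruction to ~1e−14), at the cost of wrap-around leakage that is
  negligible for 120 s windows.
* Sample entropy uses the common `n − m` template count for both
  dimensions and excludes self-matches; a constant series yields 0 by
  the exact-tie convention, and undefined cases (no matches) are
  flagged rather than forced.
* Degenerate ANOVA designs: zero between-condition variance gives
  F = 0 (p = 1); zero error variance with a non-zero effect is flagged
  undefined rather than reported as an infinite F.
* LF/HF is reported as undefined when HF is exactly zero; trial-level
  tables keep NA for undefined features and the cross-validation stage
  imputes them with training-fold medians (never test statistics).
* Seeds: every stochastic component (generation, folds, validation
  split, weight initialization, dropout, batch order, baseline
  bootstraps) draws from a deterministic stream derived from one master
  seed; re-running any stage with the same configuration is
  bit-reproducible.

# Problem sizes

All shipped analyses and tests run on one CPU. The default experiment
is the full study design (360 trials of 120 s; feature extraction takes
a few minutes). Monte-Carlo checks use 20–100 replications per
property (asymmetry recovery, detector sensitivity, event-count
exactness, null selection rate at 500 replications), sizes at which the
asserted tolerances are comfortably outside sampling noise. Unit tests
for the numerical cores run on small random instances (series of length
20–30 against a brute-force entropy oracle; 3–4-unit networks against a
per-equation reference and finite differences).

# Known limitations

* The generator's class-constant parameters make the sequence axis
  nearly uninformative beyond averaging; the recurrent model's
  advantage over well-tuned static baselines is accordingly small on
  synthetic data.
* Manual independent-component artifact removal is replaced by
  amplitude-threshold rejection plus bad-channel exclusion; trials a
  human rater would have repaired are instead dropped.
* The LF/HF feature is heavy-tailed when the HF partition is small;
  standardization does not tame single extreme trials, which mildly
  penalizes margin-based baselines.
* Tukey's HSD uses the omnibus repeated-measures error term; per-pair
  error terms (more robust under sphericity violations) are not
  implemented.
* NS.SCR counts are reported per window, not per minute; window lengths
  must be compared like for like.
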