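# emofuse

Three-class emotion recognition (positive / neutral / negative) from
synchronized physiological signals — prefrontal EEG, ECG and galvanic
skin response — with a PCA-LSTM fusion classifier evaluated under
leakage-free nested cross-validation. Intended for psychophysiology and
affective-computing researchers who need a fully testable, end-to-end
reference implementation of this analysis style, including a
synthetic-data generator with known ground truth for every stage.

## What it computes

Eleven features per 120 s trial:

* **EEG** — frontal alpha asymmetry over three homologous pairs,
  `AI = ln(P_α,right) − ln(P_α,left)`, with alpha power from a
  five-level db4 wavelet-packet decomposition (8–14 Hz nodes at 128 Hz);
* **ECG/HRV** — SDNN, RMSSD, LF and HF band powers (0.04–0.15 /
  0.15–0.40 Hz, Welch periodogram of the 4 Hz spline-resampled NN
  tachogram), LF/HF, and sample entropy (m = 2, r = 0.2·SD), all on the
  Pan-Tompkins-detected, ectopic-corrected normal-to-normal series;
* **GSR** — tonic skin conductance level and the count of non-specific
  skin conductance responses (trough-to-peak, 0.01 µS minimum
  amplitude) on the 0.3 Hz low-passed, within-participant Z-scored
  signal.

Features are screened per cross-validation fold with a one-way
repeated-measures ANOVA (Greenhouse–Geisser corrected, α = 0.05) on the
fold's training trials only, fused by concatenation, standardized,
reduced by PCA to the smallest k explaining ≥ 90% of variance, and
classified from a 4-step windowed feature sequence (60 s windows, 20 s
hop) by an LSTM (96 hidden units; FC 128–64–32 with dropout
0.4/0.3/0.2; Adam, learning rate 0.001, early stopping), implemented
from the gate equations

    f_t = σ(W_f·[h_{t−1}, x_t] + b_f)        i_t = σ(W_i·[h_{t−1}, x_t] + b_i)
    c̃_t = tanh(W_c·[h_{t−1}, x_t] + b_c)     c_t = f_t ⊙ c_{t−1} + i_t ⊙ c̃_t
    o_t = σ(W_o·[h_{t−1}, x_t] + b_o)        h_t = o_t ⊙ tanh(c_t)

SVM, random forest, kNN and XGBoost baselines are evaluated on identical
fold inputs, and models are compared with paired t-tests (Bonferroni,
paired Cohen's d) over the shared folds.

## Worked example

A small synthetic experiment end to end (4 participants × 18 trials;
the study-scale default is `synth_config()` with 20):

```r
library(emofuse)

cfg <- synth_config(n_participants = 4, seed = 7)
fx  <- extract_features_experiment(cfg)
fx$trial_table[1:3, c("participant","label","AI_F4F3","SDNN","LF_HF","SampEn","SCL","NS_SCRs")]
#>  participant    label AI_F4F3 SDNN LF_HF SampEn    SCL NS_SCRs
#>            1 positive  0.5311 36.1  1.53   2.34 -0.584       5
#>            1 negative -0.1780 33.8  4.01   1.61  0.458       7
#>            1 positive -0.0339 51.6  1.24   2.28 -1.212       5
```

Each row is one trial: the dorsolateral asymmetry index (ln-power
units), SDNN in ms, the LF/HF ratio, sample entropy, tonic conductance
in within-participant z-units and the response count. Group-level
repeated-measures ANOVA on participant × condition means:

```r
gs <- group_stats(fx$trial_table, measures = c("AI_F4F3", "SDNN", "SCL"))
#> AI_F4F3  F(2, 6) = 24.48, p_GG = 0.00704, eta^2 = 0.89
#> SDNN     F(2, 6) = 38.74, p_GG = 0.0025,  eta^2 = 0.93
#> SCL      F(2, 6) = 18.68, p_GG = 0.0165,  eta^2 = 0.86
```

All three injected contrasts are detected even at n = 4 (df2 = 6).
Nested cross-validation of all five models on the same tables:

```r
cv <- run_nested_cv(fx$trial_table, fx$window_table, seed = 1)
cv$summary
#> lstm  78.7% +/- 8.7%
#> svm   83.0% +/- 7.1%
#> rf    77.3% +/- 12.1%
#> knn   79.0% +/- 5.2%
#> xgb   65.7% +/- 18.5%
```

At this toy size (≈ 14 trials per fold) fold noise dominates; at the
default 20-participant configuration the PCA-LSTM reaches the high-80s
(%) with the permuted-label control at chance (see
`analysis/04_nested_cv.R`). Inside each fold the screening typically
keeps 8–10 informative features, which PCA compresses to 5–7
components (`cv$folds[[1]]$selected`, `cv$folds[[1]]$k`).

## The analysis workflow

Numbered drivers under `analysis/` run the full study-scale pipeline
and write their tables under `results/`:

1. `01_simulate.R` — demonstration trial set on disk (CSV/JSON) plus
   the full design manifest;
2. `02_extract.R` — preprocessing + feature extraction for all 360
   trials (trial-level and windowed TSVs);
3. `03_group_stats.R` — repeated-measures ANOVA + Tukey HSD for all 11
   features;
4. `04_nested_cv.R` — nested five-fold evaluation of PCA-LSTM and the
   four baselines, permuted-label control, pooled per-class metrics;
5. `05_model_comparison.R` — paired t-tests with Bonferroni correction
   and Cohen's d.

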