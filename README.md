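# relcen

Channel selection for motor-imagery EEG: find the smallest set of scalp
electrodes that yields the best classification accuracy.

Imagined movement suppresses mu (8–12 Hz) and beta (18–26 Hz) rhythm power
over contralateral sensorimotor cortex (event-related desynchronization).
A cap records tens of channels, but noisy and redundant channels hurt both
classifier accuracy and hardware cost. `relcen` implements a full selection
pipeline for brain–computer-interface researchers working with epoched
multichannel EEG:

1. **Surface Laplacian** spatial filter,
   `V_j^Lap = V_j − (1/n) Σ_{k∈S_j} V_k`, with a bundled 10–20 montage
   (4 neighbors interior, 2–3 at the cap periphery).
2. **Constant-Q band powers**: 13 overlapping sub-bands covering 5–35 Hz
   (centers `6·(8/7)^(k−1)` Hz, edges ±12.5 % of center; band 1 =
   5.25–6.75 Hz, band 13 = 26.07–33.51 Hz). Each feature is the trial-mean
   Hilbert envelope of one band of one channel — 13 × C features — min–max
   normalized to [−1, 1] on training data.
3. **Iterative centered Relief**: Relieff feature weighting
   (`W(f) −= Σ d(f,R,H_j)/(mk)` for near hits,
   `W(f) += Σ_C [p(C)/(1−p(class R))] Σ d(f,R,M_j(C))/(mk)` for near
   misses) with two robustness changes — target samples are taken in order
   of distance to their class center instead of at random, and the N
   lowest-weight features are eliminated per pass with all distances
   recomputed on the survivors, until the feature set is empty.
4. **Tenfold cross-validated RBF-SVM** scoring of every surviving set
   (selection and normalization run inside training folds only). The
   *optimal channels* are the smallest channel set among the steps tying
   the best mean accuracy; a channel counts as selected as soon as one of
   its 13 bands survives.

A synthetic generator plants contralateral mu-band ERD in known channels so
that every stage is testable without data downloads.

## Worked example

```r
library(relcen)

bench <- default_benchmark(seed = 1)   # 4 planted ERD channels: 6, 8, 13, 15
bench$trials
#> TrialSet: 200 trials x 20 channels x 600 samples @ 200 Hz
#>   classes: 1 (n=100), 2 (n=100)

fm <- extract_features(bench$trials, design_constant_q_bank())
fm
#> FeatureMatrix: 200 trials x 260 features (13 bands/channel)

cw <- channel_weights(minmax_normalize(fm), relief_config(k = 10))
round(cw, 3)
#>  [1] -0.023 -0.023  0.029 -0.015  0.029  1.010  0.009  0.839  0.019  0.005
#> [11]  0.029 -0.030  0.910 -0.014  0.859  0.030  0.050  0.001  0.057 -0.024
order(-cw)[1:4]
#> [1]  6 13 15  8

cv <- run_selection_cv(fm, relief_config(k = 10), svm_config(),
                       N = 26, k = 10, seed = 1, inner_folds = 0)
opt <- select_optimal(cv, fm, relief_config(k = 10))
opt$channels
#> [1]  1  3  6  8 13 15 19
opt$accuracy
#> [1] 1
opt$bands_per_channel[["6"]]
#> [1] 2 3 4 5 6 7
```

The one-pass channel weights separate the four planted channels (0.84–1.01)
from the sixteen noise channels (|w| ≤ 0.06) by more than an order of
magnitude, and the cross-validated selection returns a 7-channel optimal set
containing all four planted channels, each retaining the bands that overlap
the planted 8–12 Hz effect (bands 3–7 span 6.9–15.0 Hz). The accuracy of
1.0 reflects the benchmark's deliberately clear effect size, not an
expectation for real recordings.

Input handling for real data: `read_edf()` / `epoch_recording()` for EDF,
`read_matrix()` for a CSV + YAML-sidecar matrix format, `load_montage()`
for montage files (see `inst/extdata/montage_1020.yaml`), `downsample()`
and `crop_execution()` for rate and execution-window preprocessing. A thin
command-line front end lives at `inst/cli/relcen.R`
(`Rscript inst/cli/relcen.R simulate|select ...`).

## Package layout

- `R/core-data.R` — `TrialSet`, `Recording`, `Montage`, matrix I/O
- `R/edf.R` — minimal EDF reader/writer (16-bit, equal-rate signals)
- `R/preprocess.R` — `downsample()`, `crop_execution()`, `laplacian_filter()`
- `R/feature-bank.R` — `design_constant_q_bank()`, `bandpass()`,
  `hilbert_envelope()`, `extract_features()`, `minmax_normalize()`
- `R/relief.R` — `relieff_weights()`, `class_center_order()`,
  `iterrelcen()`, `features_to_channels()`
- `R/evaluation.R` — `stratified_folds()`, `train_eval_svm()`,
  `run_selection_cv()`, `select_optimal()`, `accuracy_vs_channels()`,
  `channel_weight_map()`, `band_usage_counts()`
- `R/synthetic.R` — `synthetic_spec()`, `generate_synthetic()`,
  `default_benchmark()`
- `vignettes/channel-selection.Rmd` — the model, its assumptions, and all
  numerical design choices
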