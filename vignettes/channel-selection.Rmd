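---
title: "Selecting optimal EEG channels with iterative centered Relief"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting optimal EEG channels with iterative centered Relief}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Sensorimotor-rhythm brain-computer interfaces decode imagined movement from
multichannel EEG. Imagined movement of a limb suppresses the power of the mu
(8--12 Hz) and beta (18--26 Hz) rhythms over the contralateral sensorimotor
cortex -- event-related desynchronization (ERD). A cap records tens of
electrodes, but most channels carry noise or redundant copies of their
neighbors' activity; classifiers trained on all of them perform worse than
classifiers trained on a well-chosen subset, and every extra electrode costs
setup time and money. Channel selection asks: *which is the smallest channel
set that yields the best classification accuracy?*

`relcen` implements a complete selection pipeline: spatial sharpening,
band-power feature extraction, Relief-family feature weighting with two
robustness modifications, and cross-validated SVM evaluation of every
candidate feature set.

## The pipeline

### Surface Laplacian

Scalp EEG is spatially smeared by volume conduction. The surface Laplacian
re-references every channel against the mean of its neighbors,

$$V_j^{Lap} = V_j - \frac{1}{n}\sum_{k \in S_j} V_k,$$

where $S_j$ holds the $n$ neighboring electrodes of channel $j$. The bundled
10--20 montage (`default_montage()`) uses 4 grid neighbors for interior
electrodes and the available 2--3 for electrodes at the cap periphery. All
channels are transformed simultaneously from the raw input; a sequential
in-place update would let already-filtered values contaminate later
channels.

### Constant-Q band-power features

The 5--35 Hz range that carries motor-imagery information is divided into 13
overlapping constant-Q (proportional-bandwidth) sub-bands: center $k$ is
$6 \times (8/7)^{k-1}$ Hz and each band spans $\pm 12.5\%$ of its center
(`design_constant_q_bank()`). Low-frequency rhythms are narrow and
high-frequency rhythms broad, so proportional widths sample both naturally;
because $\tfrac{8}{7}\cdot\tfrac{7}{8} = 1$, each band's lower edge
coincides with the previous band's center, giving seamless overlap from
5.25 Hz up to 33.51 Hz.

Each trial, channel, and band yields one feature: the trial-mean Hilbert
envelope of the band-passed signal, which tracks average band power during
the trial. With $C$ channels this gives $13C$ features per trial (767 for a
59-channel cap, 806 for 62), concatenated channel-major. Features are then
min--max normalized to $[-1, 1]$:

$$X_N = (newMax - newMin)\,\frac{X - Min}{Max - Min} + newMin .$$

Normalization parameters are always fitted on training folds only and
applied unchanged to held-out folds (values may then exceed the range and
are left unclipped); fitting them globally would leak test-set information
into the classifier's scale.

### Relieff weighting

Relieff scores a feature by how well it separates nearby samples of
different classes. For each target sample $R$, the algorithm finds its $k$
nearest same-class neighbors (near hits) and $k$ nearest neighbors in every
other class (near misses), and updates

$$W(f) \mathrel{-}= \frac{\sum_j d(f,R,H_j)}{m\,k}, \qquad
  W(f) \mathrel{+}= \sum_{C \neq class(R)}
  \frac{p(C)}{1 - p(class(R))}\,\frac{\sum_j d(f,R,M_j(C))}{m\,k},$$

with per-feature differences normalized by the feature's training range,
$d(f,R,R') = |x_{Rf} - x_{R'f}| / (\max_f - \min_f)$. A feature whose
nearest misses are farther than its nearest hits earns positive weight. On
normalized input every weight lies in $[-1, 1]$, and two classes reduce the
update to classic Relief.

### Iterative centered elimination

Plain Relieff has two noise sensitivities: targets are sampled at random, so
outlying samples can become targets and bias the update; and distances are
computed over *all* features, so noisy features corrupt the neighbor search
itself. `iterrelcen()` addresses both:

1. **Centered targets.** Targets are taken deterministically in order of
   distance to their class center ($Ct = \tfrac{1}{n}\sum S_i$), so the most
   typical samples anchor the weighting. The per-class allotment is
   proportional, $m_c = \mathrm{round}(m\,n_c/n)$; with the default $m$
   equal to the training size this means every sample is used, in a fixed
   order.
2. **Iterative elimination.** After each weighting pass the $N$
   lowest-weight features are removed and *everything* -- feature ranges,
   class centers, neighbor distances -- is recomputed on the survivors. As
   noisy features disappear, the distance metric reflects the true sample
   geometry increasingly well. The loop runs until the feature set is
   empty, evaluating every surviving set (including the initial full set)
   along the way, in $\lceil F/N \rceil$ iterations.

The loop contains no randomness; identical inputs give identical traces.
Ties -- in neighbor search, center ordering, and removal -- always break by
ascending index.

### Evaluation and optimal channels

`run_selection_cv()` wraps the selection in stratified tenfold
cross-validation: per fold, normalization and selection see only the
training portion (the selection's internal evaluator is 5-fold CV inside
the training fold), and the held-out fold is scored at every elimination
step with an RBF-kernel SVM (one-against-one for multiclass, so $K$ classes
train $K(K-1)/2$ pairwise machines). The reported accuracy per step is the
exact mean of fold accuracies.

"Optimal" is best accuracy with fewest channels: among the steps tying the
maximal mean accuracy, `select_optimal()` picks the one spanning the
smallest channel set; a channel is selected as soon as one of its 13 bands
survives, so optimal channels may retain anywhere between 1 and 13 bands.
Because folds generally disagree on feature identities, the reported
identities come from one final full-data selection pass at the chosen step
size -- the accuracy stays the honest cross-validated estimate, the
identities are a point estimate, and both are reported.

For accuracy-versus-channel-count curves, channels are ranked by the summed
feature weights of the first (full-set) weighting pass and added one by one,
all 13 bands at a time.

## Numerical and design choices

- **Band-pass realization.** The sub-band filter is specified by its
  magnitude response, not an implementation: `bandpass()` applies the
  squared magnitude of a 4th-order digital Butterworth (zero phase,
  monotonic passband, about 48 dB/octave effective roll-off) in the
  frequency domain on an even-reflected extension of each trial. The
  reflection removes the circular-wrap discontinuity, and a forward-backward
  time-domain filter of the same prototype converges to the same response as
  transients vanish. With 3-s windows the residual edge ripple for the
  narrowest band (5.25--6.75 Hz) is a few percent, immaterial to
  trial-averaged features.
- **Envelope.** The Hilbert envelope uses the plain circular FFT analytic
  signal. Reflection padding deliberately is *not* used here: time-reversing
  an oscillation flips its phase progression, which distorts the analytic
  signal near the junction; the circular version is exact for in-window
  periodic components and its wrap error stays confined to the trial ends.
  Features average the envelope over the full trial, without trimming.
- **Anti-aliasing.** `downsample()` only supports integer factors and
  low-passes at 0.4 times the target rate with a zero-phase Hamming-window
  FIR (>50 dB stopband) before decimating -- a safe default, since nothing
  about aliasing is otherwise enforced.
- **Cropping convention.** `crop_execution()` takes half-open windows
  `[start, end)` with floor-based sample indexing; only the execution
  period of a control-paradigm trial (typically 0.5--3 s) carries
  motor-imagery modulation. The window is an explicit argument because its
  anchor (cue vs. feedback onset) is paradigm-specific.
- **Degenerate features.** A constant feature cannot separate anything: its
  normalized value is the range midpoint (with a warning) and its Relieff
  difference is defined as 0, so its weight is exactly 0.
- **SVM settings.** Defaults are $C = 1$ and $\gamma = 1/F$; the paper-style
  protocol leaves them unstated and results are insensitive at the planted
  effect sizes used here. An optional 3-fold log-grid search over $C$
  (`svm_config(tune_C = TRUE)`) runs inside the training fold only.
- **Indexing.** All trial, channel, band and feature indices are 1-based,
  following R convention, with the channel-major feature layout
  `feature = (channel - 1) * 13 + band`.

## The synthetic benchmark

Real motor-imagery corpora are subject-bound and rarely redistributable, so
the package ships a generator (`generate_synthetic()`) whose defaults define
the conditions every recovery experiment uses. Each channel is the sum of
pink background activity (PSD $\propto 1/f$, RMS 0.5), white sensor noise
(SD 0.25), and an ongoing band-limited oscillation (RMS 1.0). At the
informative channels of a class, the oscillation amplitude is multiplied by
an attenuation factor during that class's trials -- ERD modeled as amplitude
suppression of ongoing activity, the simplest mechanism producing the
class-dependent band-power decrease that drives selection.

`default_benchmark()` is the canonical fixture: 20 channels, 2 classes of
100 trials, 200 Hz, 3-s trials, mu-band (8--12 Hz) attenuation 0.5 at
channels 6 and 8 for class 1 and channels 13 and 15 for class 2 -- a
contralateral pair per imagined hand. Amplitude attenuation 0.5 means the
planted channels' in-band power ratio between classes is about 0.25 plus the
background floor.

What the generator does *not* emulate: volume-conducted correlation between
channels, artifacts (EOG/EMG), non-stationary rhythms, evoked components, or
subject variability. Passing the recovery experiments therefore shows the
algorithmic chain is sound -- planted effects of realistic size are found,
permuted labels are not -- but says nothing about accuracy levels on real
recordings.

Problem sizes used in the validation experiments: planted-channel recovery
runs the full pipeline on 20 generator seeds of the benchmark and requires
the 4 planted channels to be the top 4 by channel weight in at least 90% of
seeds; accuracy-vs-channel curves are checked on 2 seeds; the permutation
(leakage) control runs the cross-validated selection once on a
label-shuffled benchmark and requires the peak step accuracy to stay inside
a Bonferroni-adjusted binomial chance bound at $p > 0.01$. These sizes keep
a full validation run in minutes while leaving the binomial and recovery
margins wide.

## Known limitations

- The iterative loop re-trains an evaluator per elimination step and per
  fold; it is an offline analysis tool, not a real-time (online) selector.
- EDF support covers the common equal-rate EEG case; mixed per-signal rates
  and annotation decoding are out of scope, as are BrainVision/GDF/FIF
  readers.
- The electrode identities of any particular recording setup must come from
  the user's montage file; the bundled 61-electrode 10--20 grid is a
  faithful schematic stand-in, not a reconstruction of any specific cap.
- Comparison selectors (mRMR, SVM-RFE, CSP variants) are not implemented.

## A compact session

```{r, eval = FALSE}
library(relcen)

bench <- default_benchmark(seed = 1)
fm <- extract_features(bench$trials, design_constant_q_bank())

# channel ranking from one centered weighting pass
cw <- channel_weights(minmax_normalize(fm), relief_config(k = 10))
order(-cw)[1:4]          # recovers channels 6, 8, 13, 15

# cross-validated selection and the optimal set
cv <- run_selection_cv(fm, relief_config(k = 10), svm_config(),
                       N = 26, k = 10, seed = 1)
opt <- select_optimal(cv, fm, relief_config(k = 10))
length(opt$channels); opt$accuracy
```
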