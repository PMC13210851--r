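---
title: "Methods: synthetic gait cohorts, sequence classifiers, and the evaluation suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gait cohorts, sequence classifiers, and the evaluation suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

gaitshift implements a complete, seeded pipeline for a six-class gait
classification task: a smartphone in a trouser pocket records tri-axial
acceleration at 50 Hz while a person walks a fixed route either
unimpaired ("none") or wearing one of five alcohol-impairment simulation
goggles whose strap colours (green, blue, black, red, orange) encode
increasing manufacturer-declared simulated blood-alcohol ranges, up to
0.26–0.35% for orange. The classifier must recognise, from short windows
of the acceleration signal, which condition a walk belongs to.

Because the underlying field recordings are not publicly deposited, the
package is built around a synthetic cohort generator that reproduces the
*statistical structure* of such a study — cohort layout, signal format,
preprocessing challenges, and condition effects that grow gradually with
simulated impairment — so that every downstream stage is testable
end-to-end without any external data.

# The synthetic cohort generator

## Signal model

Each traversal is a harmonic gait signal with per-step timing jitter,
not a biomechanical simulation. Step boundary times are generated as

$$ \tau_i = \frac{1}{f_{\text{step}}}\,(1 + c_v\,\varepsilon_i), \qquad
   \varepsilon_i \sim \mathcal N(0,1), $$

and a piecewise-linear phase $\varphi(t)$ advances by $2\pi$ per step.
The vertical axis carries gravity plus step-frequency harmonics
($\sin\varphi$, $\sin 2\varphi$, $\sin 3\varphi$ with fixed relative
amplitudes 1 : 0.4 : 0.15), the anteroposterior axis two harmonics, and
the mediolateral axis a stride-frequency oscillation ($\varphi/2$,
because legs alternate) plus autocorrelated sway noise (AR(1),
coefficient 0.95). A fixed rotation models imperfect pocket
orientation; gravity is rotated with the dynamic signal, so a small
fraction of it leaks into the horizontal axes, as in real pocket
recordings. Stationary low-noise pads precede and follow the active
region, and marker indices bracket it.

## What is a person, what is a condition, what is noise

The generator draws three kinds of randomness, and the distinction is
what makes the within-traversal evaluation protocol meaningful:

* **Participant traits** (drawn once per participant, shared by all six
  of their traversals): base step frequency (1.6–2.0 Hz), per-axis
  amplitudes, the relative phases of the gait harmonics, and the pocket
  orientation rotation. Harmonic phase structure is deliberately a
  *participant* trait: it persists through a traversal, so if it were
  drawn per traversal it would fingerprint each traversal and let a
  classifier trained on the first 80% of a walk identify the walk — and
  hence its label — in the last 20% even with all condition effects
  disabled. With traits at the participant level, a participant's six
  traversals are statistically identical under the null and the six
  classes are exchangeable.
* **Condition effects** (deterministic functions of severity): severity
  is the midpoint of a condition's simulated BAC range divided by the
  largest midpoint, so none = 0 and orange = 1. Step-time coefficient
  of variation is multiplied by $1 + 2.5s$, mediolateral sway amplitude
  by $1 + 4.5s$, cadence by $1 - 0.28s$, and a per-step amplitude
  irregularity grows as $0.6s$. Because oscillation at a fixed
  displacement has acceleration proportional to frequency squared, the
  cadence reduction also damps the dynamic gait amplitudes by the
  squared cadence multiplier — the cautious, lower-impact gait of an
  impaired walker. All effects are monotone in severity, neutral at
  zero, and scaled globally by `effect_scale` (0 gives the null
  cohort). The magnitudes are calibration choices, not field facts: the
  multipliers were chosen so that (a) even the strongest condition
  still *walks* — its autocorrelation periodicity stays above the
  steady-gait validity threshold, as real impaired-but-completed
  traversals must — and (b) a small BiLSTM classifier lands in a 60–85%
  test-accuracy band on the default reduced cohort, mirroring the
  gradual, adjacent-condition-confusable structure the study reports.
  They were frozen after that one calibration.
* **Per-traversal noise** (fresh every traversal): step-interval jitter
  realisations, sway noise, measurement noise (SD 0.08 m/s²), and the
  step-phase origin. None of these persists in a way that
  distinguishes one traversal of a participant from another.

## Cohort layout

The default configuration is 16 participants × 6 conditions = 96
traversals at 50 Hz. Active lengths are drawn from a scaled
Beta(1, b) on 2293–6211 samples with b solving for a mean of 3030 —
a right-skewed distribution; a uniform draw on that range would have
mean 4252, which is incompatible with the configured mean. Setting
`target_mean_length = NULL` recovers the uniform draw. Each sensor's
stream is written as a four-column CSV (`timestamp_ms`, then three
axes; milliseconds as integers, comma-separated, dot decimal), with a
YAML session manifest holding participant, condition, placement, file
paths and raw marker indices. Gyroscope channels can be emitted for
format fidelity but are never consumed by any model.

# Preprocessing

The chain is: synchronise → map markers → crop → gravity offset →
periodicity profile → steady-segment extraction.

* **Synchronisation** linearly interpolates all channels onto one
  uniform 50 Hz axis covering the overlap of the input streams. Linear
  interpolation is monotone and artefact-free at gait frequencies; at
  50 Hz its worst-case error on a 1.5 Hz component is below 1% of the
  amplitude.
* **Marker mapping** converts raw marker indices to timestamps and maps
  each to the *first* synced sample at or after it.
* **Gravity offset** subtracts 9.81 m/s² from the vertical channel
  only. No orientation normalisation is attempted; the residual gravity
  leakage from pocket orientation is retained deliberately.
* **Periodicity** slides a 2.56 s (128-sample) window over the
  acceleration magnitude (channels are demeaned first, making the
  profile invariant to constant channel offsets) and scores each window
  by its maximum normalised autocorrelation over lags of 0.4–1.5 s,
  roughly one stride. Windows hop by 0.32 s. Local maxima of the score
  sequence clearing a validity threshold of 0.4 are candidate gait
  patterns; plateau runs collapse to their first element. The window
  length, lag range, hop and threshold are package choices — standard
  values for 50 Hz gait — and are all exposed as arguments.
* **Extraction** keeps the interval from the (n_trim + 1)-th to the
  (last − n_trim)-th valid pattern, with n_trim = 3, discarding gait
  initiation and termination. Fewer than 2·n_trim + 1 valid patterns is
  a "no steady gait" error, by design: a traversal without detectable
  periodicity should fail loudly, not silently produce an empty
  segment.

# Window datasets

Each steady segment is split chronologically at
`floor(T * 0.8)` — the only reading of a non-overlapping
within-traversal 80/20 protocol — and each part is windowed
*independently* with 256-sample windows (5.12 s) and stride 4, so no
window straddles the split and train/test never share a sample. Only
training windows are augmented: each original is kept and `n_augmented`
noisy copies are added with i.i.d. zero-mean Gaussian noise (variance
0.2 by default; the alternative setting of variance 0.1 with 5 copies
is reachable via configuration). Test counts are invariant to the
augmentation settings. Cross-validation fold i takes the i-th
contiguous 1/k chunk of every traversal as test and windows the
remaining one or two pieces separately for training, which keeps the
folds' test chunks disjoint and the protocol within-traversal.

# The architecture zoo

Five sequence classifiers map a `[batch, 256, channels]` window to six
class scores. Layer conventions were fixed by reconciling every layout
against its published trainable-parameter count, which they reproduce
exactly:

| model | layout | parameters |
|---|---|---|
| A1 | Conv1D(in→64, k3) → global average pool → dropout → FC 64→6 | 1,030 |
| A2 | BiLSTM(in→32×2) → dropout → FC 64→6 | 9,862 |
| A3 | Conv1D ×3 → LN (affine-free) → BiLSTM → dropout → FC | 50,822 |
| A4 | Conv1D ×2 → parameter-free self-attention → LN (affine-free) → BiLSTM → dropout → FC | 38,470 |
| A5 | Conv1D ×2 → 2 × [projected self-attention + affine LN] → BiLSTM → dropout → FC | 72,006 |

The count-determined conventions: convolutions are kernel 3, stride 1,
length-preserving, with bias and ReLU (a kernel of 5 is irreconcilable
with every printed count, including the 192-parameters-per-channel
ablation ladder, so kernel 3 it is); the BiLSTM has 32 hidden units per
direction with two bias vectors per gate block; A4's four-head
attention is pure scaled dot-product over head-reshaped features with
no learned tensors; each A5 attention block carries learned
Q/K/V/output projections (64×64 + 64 each) plus one elementwise-affine
layer norm (16,768 parameters per block); the head takes the 64-value
concatenation of both LSTM directions' hidden states, mean-pooled over
time, through dropout (p = 0.2) into an affine 64→6 map. Mean pooling
was chosen among the parameter-neutral readout options (final states,
max, mean) because the class-discriminative features here are
window-level statistics — sway variance, cadence, step-interval
irregularity — which a time average of hidden states represents far
better than the last state alone, and because it shortens the
effective gradient path through the 256-step recurrence. Both attention variants use
a residual connection — parameter-neutral, and it stabilises training.
A1 is listed elsewhere as three convolutions, but only a single
convolution plus the head reproduces its 1,030 parameters; the
single-conv reading is implemented. Removing an input channel removes
exactly one 3×64 slice of the first convolution: 72,006 → 71,814 →
71,622 for 3 → 2 → 1 channels.

The whole engine — forward passes, backpropagation (including
backpropagation through time entered only at the final hidden states),
softmax cross-entropy, Adam with global-norm gradient clipping at 1.0,
inverted dropout, masked-span corruption — is implemented natively on
BLAS matrix products. Every layer's analytic gradient is verified
against central finite differences in the test suite; that check is the
engine's correctness oracle.

## Training and pretraining

Training follows the study protocol: Adam at learning rate 1.5·10⁻³,
batch size 32, cross-entropy, gradient clipping, up to 20 epochs, no
early stopping, seeded shuffling. Encoder pretraining is
masked-prediction self-supervision of the convolutional stem: 15% of
time steps are zeroed in contiguous 8-sample spans (the family is
prescribed; ratio and span are package choices in line with common
masked-autoencoder practice), a mirrored transposed decoder
reconstructs the input, the loss is mean-squared error on all
positions, and after 3 epochs the decoder is discarded. Architectures
without a convolutional stem refuse pretraining with a warning rather
than silently doing nothing.

# Evaluation suite

From a confusion matrix in canonical class order the package computes
one-vs-rest precision, recall, specificity and F1 per class
(zero-denominator cases are defined as 0, which only degenerate toy
inputs hit), and the aggregates: accuracy, support-weighted F1, minimum
recall, unweighted mean F1, class balance (max recall − min recall, in
percentage points), average false-positive rate (mean over classes of
1 − specificity), and class leakage — the largest off-diagonal
row-normalised entries, rounded to whole percentages, ties broken by
(row, column) class order.

Three interval estimators mirror the study's reporting:

* **Wilson** score intervals for accuracy, with n = the number of test
  windows. Windowed samples are strongly dependent (they come from few
  traversals), so this n overstates the effective sample size and the
  interval should be read as a lower bound on the uncertainty.
* **Percentile bootstrap** (B resamples of (true, predicted) pairs with
  replacement, seeded) for recall-derived aggregates. The resampling
  unit is the prediction pair — the natural unit when only label pairs
  are available.
* **Student-t** fold summaries: mean, sample SD (n−1), and half-width
  $t_{0.975,k-1}\,s/\sqrt{k}$ across cross-validation folds.

# Orchestration and reproducibility

`run_experiment()` chains simulate → preprocess → window → (pretrain) →
train → evaluate, with optional per-fold retraining and Student-t fold
summaries; `run_ablation()` repeats one architecture over channel
subsets of the *same* prepared data. One global seed fans out to every
stage through a fixed affine hash (`derive_seed(seed, stage, index)`),
so identical configurations give identical cohorts, identical shuffles,
identical dropout masks, and byte-identical simulated files.

## Problem sizes

The standing benchmark (`reduced_benchmark_config()`) uses 6
participants × 6 conditions with 2000–3000-sample traversals, stride-16
windows, one noisy copy per training window, and 5 epochs of A2 — a few
minutes of CPU time, chosen so the full property suite (null cohort at
chance, calibrated cohort well above chance, monotone response to
effect scale) runs routinely. The statistical conclusions do not
depend on these sizes; they are the package's default operating point
for its own tests.

The null-cohort check uses a binomial band around 1/6 with n equal to
the number of test *traversals*, not test windows: windows within a
traversal are strongly dependent (a model typically predicts one label
for most windows of a traversal), so the traversal is the independent
unit and a window-level band would have far less than nominal coverage.

# What passing tests do and do not show

The generator reproduces the cohort structure, the file formats, the
preprocessing challenges (pads, jittered timestamps, gravity leakage),
gradual monotone condition effects, and the dependence structure that
makes within-traversal evaluation optimistic. It does not reproduce
real biomechanics: no double-support dynamics, no turning, no pauses,
no device slippage, no inter-device asynchrony beyond timestamp jitter,
and condition effect *sizes* in signal space are calibration choices.
Passing the suite therefore validates the pipeline's correctness and
its statistical machinery — not any claim about how accurately real
goggle-impaired gait can be classified, which only the original (not
deposited) field data could support. The published headline accuracies
are correspondingly not targets of this package's tests.

Known limitations: no orientation normalisation (inherited from the
protocol being emulated); the LOSO (leave-one-subject-out) split is
deliberately out of scope; training on one CPU in native R is
practical at benchmark sizes but not at the study's full window counts
(hundreds of thousands of augmented windows).
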