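---
title: "Detecting slow muscle activation onsets: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting slow muscle activation onsets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowonset)
```

## The problem

Surface EMG onset detection is usually benchmarked on brisk, ballistic
contractions, where the signal jumps from baseline noise to a high-amplitude
burst and almost any threshold rule works. Slow, voluntary activation - the
regime of rehabilitation training, assistive control and monitoring of older
adults - looks different: the amplitude envelope rises over hundreds of
milliseconds, the plateau sits only a few dB above the resting noise, and
there is no abrupt change for a derivative- or threshold-based detector to
latch onto. `slowonset` implements a lightweight temporal-attention detector
for this regime, together with the full preprocessing, training, decision and
evaluation pipeline and a synthetic data generator, so every stage is
testable without access to recorded data.

## Signal model and preprocessing

A trial is a `channels x samples` real matrix at sampling rate `fs`
(default 1000 Hz). Preprocessing follows the standard sEMG chain:

1. **Band-pass filtering**, 20-450 Hz Butterworth of total order 4,
   implemented as a cascade of second-order sections because the upper edge
   sits close to the Nyquist frequency at 1 kHz sampling. The default is
   zero-phase (forward-backward) filtering so that filter delay cannot bias
   onset labels; a causal single-pass mode exists for streaming use, and its
   group delay is the user's responsibility. When `fs <= 900` Hz the upper
   cutoff is clamped to `0.45 * fs` with a warning. Zero-phase filtering
   pads each channel with an odd reflection (three periods of the slowest
   pole) before filtering: without the warm-up, the filter's startup
   transient deposits an artificial amplitude burst in the first tens of
   milliseconds of every trial, which any amplitude-sensitive detector
   happily mistakes for activation.
2. **Trial-level z-scoring**: each channel is standardized by its whole-trial
   mean and standard deviation. Normalization is global, never
   window-local, so the slow macroscopic amplitude trend - the very thing to
   be detected - survives. A channel with standard deviation below `1e-9`
   is rejected as degenerate rather than silently inflated.
3. **Sliding windows** of `L = 250` ms with stride `S = 50` ms, half-open
   `[kS, kS + L)`, trailing partial window dropped. A window is *labelled*
   active only when its overlap with the annotated activation interval
   strictly exceeds `L/2`; these 50%-rule labels are used for bookkeeping
   metrics. The training loss instead uses the per-sample activity
   indicator, because the network emits a per-sample confidence curve.

Indices are 1-based in the R API; all times are milliseconds from trial
start, so sample `i` lives at `(i - 1) / fs * 1000` ms.

## The detection network

The detector maps a preprocessed window `X (C x T)` to a confidence trace
`y_t` in `[0, 1]`, one value per sample:

* **Encoder** - one causal width-5 convolution to `C' = 28` channels
  (output at `t` reads `t-4 .. t`), plus a 1x1 channel map that stabilizes
  the feature distribution. Deliberately shallow and linear: its job is
  denoising and compression, not abstraction.
* **Temporal attention** - for every `t`, the local context
  `Z_t = Concat(F[, t-k : t+k], F[, t])` with neighbourhood radius `k = 2`
  is transformed by two shared width-3 convolutions (to `Ca = 32` channels,
  ReLU, then to `Cb = 16`) and a 1x1 projection, and squashed by a sigmoid
  into a scalar weight `alpha_t` in `[0, 1]` that multiplies the feature
  column: slow, persistent trends are amplified, isolated fluctuations are
  not. Because every step is a stride-1 convolution, cost is linear in `T`,
  unlike the quadratic cost of inner-product attention.
* **Stable decision stack** - three gated units; each computes two parallel
  width-3 convolutions `U_t`, `V_t` of its input and returns
  `tanh(U_t) * sigmoid(V_t)`. The bounded smoothing nonlinearity gated by a
  bounded gate behaves as an adaptive low-pass: spikes are attenuated layer
  by layer while slow components pass.
* **Confidence head** - 1x1 projection to width 21, ReLU, 1x1 projection to
  one channel, sigmoid.

### Edge convention

All width-3 convolutions use same-length zero padding. For the attention
block the context-concatenation followed by a width-3 convolution is fused
into a single 7-tap convolution over the feature map; correspondingly,
context blocks that extend past the window edge are built from the
zero-padded feature map. The per-timestep oracle tests pin this convention
down exactly.

### Parameter budget and width calibration

The attention widths (32/16), radius (2), the unit width (16) and the unit
count (3) are architectural constants. The encoder width, the first unit's
width and the head width are free, and are fixed by a parameter budget of
**24,580 trainable parameters** for the assembled network.
`calibrate_net_widths()` enumerates small integer widths (and the encoder
depth/kernel options), keeps combinations that hit the budget exactly, and
prefers the solution closest to the canonical widths (encoder near 32,
unit/head near 16, two encoder layers, kernel 5). The unique optimum -
encoder 28 channels / kernel 5 / 2 layers, first unit 12, head 21 - is
frozen as the `net_config()` defaults, and the budget is re-checked by the
test suite:

```{r}
count_parameters(net_config())
```

### Initialization

Weights are drawn from the fan-in-scaled uniform
`U(-sqrt(3/fan_in), sqrt(3/fan_in))`, which preserves activation variance
through the linear layers; biases start at zero. The naive
`1/sqrt(fan_in)` scale shrinks activations threefold per layer, and after
three gated units the confidence head would see gradients too small to
train at the configured learning rate.

## Decision rule

The per-window traces are stitched to a trial-level curve (each sample
averages all windows covering it), and activation is declared at the first
time `t` where the mean confidence over the **trailing** window of
`|Omega| = 100` ms strictly exceeds `theta = 0.75`. A trailing window keeps
the rule causal; a centred one would anticipate the onset. The reported
onset is the trigger time itself, with no back-correction, so the delay
metric measures exactly the decision lag. An isolated confidence spike
cannot trigger the rule: with i.i.d. sub-threshold noise the false-trigger
probability falls rapidly as the window grows, a property the test suite
checks empirically at `|Omega|` of 5, 25 and 50 samples.

Both `theta` (grid 0.50-0.90, step 0.05) and `|Omega|` (grid 50/100/150/200
ms) are tuned once on validation trials by exhaustive search - minimum mean
onset detection error, ties broken by lower rest-window false-positive
rate, then by the smaller threshold and window - and then frozen across all
test subjects. A candidate that never detects scores infinitely badly.
Equality at floating-point resolution does not trigger the strict
inequality (a `1e-9` guard absorbs accumulated summation fuzz).

## Training protocol

Mini-batch SGD, batch 128 windows, initial learning rate 0.001, Nesterov
momentum 0.9, weight decay 1e-4. The learning rate halves when the
validation loss fails to improve for 5 consecutive epochs; training stops
after 15 epochs without improvement (hard cap 200), restoring the best
checkpoint. All randomness (initialization, shuffling, augmentation) derives
from one global seed, 42 by default, through a documented counter scheme
(`substream_seed()`), and a fixed seed reproduces weights bit-exactly in
single-threaded mode.

The loss is per-sample binary cross-entropy between the confidence trace
and the activity indicator. For the *gradient*, the per-sample loss is
summed over the window's time axis and averaged over the mini-batch - the
usual sequence-labelling normalization. Averaging over all samples instead
would scale gradients down by the window length and make the configured
learning rate ineffective; reported losses remain per-sample means so they
are comparable across window lengths.

Two lightweight augmentations run at training time only: amplitude scaling
with `alpha ~ U(0.8, 1.2)` applied to windows on the fly, and whole-trial
temporal scaling with `beta ~ U(0.8, 1.25)` under which the onset label is
multiplied by exactly the same factor. Temporal scaling resamples the trial
(linear interpolation), cropping the tail for `beta > 1` and zero-padding it
for `beta < 1`; a draw whose scaled onset leaves the trial is rejected. A
full resample back to the original duration would undo the time scaling and
contradict the label rule, which is why the crop/pad reading is used.
Evaluation data are never augmented.

Data splits are always subject-wise: `make_subject_folds()` partitions
subjects (never trials) into folds, leave-one-subject-out being the
degenerate case of one subject per fold; a 70/15/15 split is available for
single-run experiments, while subject-wise cross-validation is the
reporting protocol. Any subject overlap between training and validation
sets is a hard error, and the no-leakage property is tested over random
fold plans.

One consequence of trial-level z-scoring deserves emphasis: an
activation-free trial is rescaled to unit variance, which makes it
mathematically indistinguishable from a trial of sustained activity - the
scale information that separates them is exactly what the normalization
removes. The learned detector is therefore fitted on trials that contain a
rest-to-activation transition; feeding all-rest trials to the loss teaches
the network that unit amplitude means rest and biases the decision boundary
upward (measured on the packaged benchmark: detection delays grow by
roughly 200 ms). Rest trials remain first-class citizens everywhere else -
decision-rule tuning, false-positive accounting and the benchmark
evaluation all use them.

## Metrics

Over trials where both ground truth and a prediction exist:
`ODE = mean |t_pred - t_gt|` and `Delay = mean max(0, t_pred - t_gt)`
(so `Delay <= ODE` algebraically). Trials with an annotated onset but no
detection are excluded from those means and reported as a `miss_rate`,
since the error of an absent prediction is undefined. The false-positive
rate is window-level: a rest window counts as a false positive when the
detector's stitched decision marks any of its samples active, and
`FPR = N_fp / (N_fp + N_tn)`. The real-time factor (processing time over
signal duration) is measured and reported but is hardware-dependent, so no
test asserts a specific value. Window-level accuracy/precision/recall use
the 50%-rule labels.

## The synthetic generator

`simulate_dataset()` emulates the defining features of slow-activation
recordings: a white-Gaussian carrier shaped by the same 20-450 Hz band-pass
used in preprocessing (matching the sEMG band without modelling motor-unit
physiology), multiplied by `gain * (1 + (10^(SNR/20) - 1) * envelope(t))`.
The envelope is a cubic smoothstep - exactly zero before the ramp start, so
the generative ground truth is well defined, unlike a logistic which never
reaches zero - rising over 300-1500 ms and then sustained to the end of the
trial, mirroring a rest-to-held-contraction protocol. Per-subject amplitude
scales are lognormal (`sdlog` 0.3); channels get up to 30 ms of onset
jitter with the earliest channel defining the ground truth; noise tiers
low/medium/high default to 16/10/4 dB plateau-to-rest RMS (the tiers are
configuration, not constants, because no canonical values exist for them).
Rest trials (default 25%) carry no envelope.

What the generator does *not* reproduce: motor-unit action potentials and
their recruitment statistics, electrode lift-off and motion artifacts,
power-line interference, non-stationary baseline drift, or cross-channel
correlation structure beyond shared onset timing. Passing tests on this
generator therefore demonstrate the pipeline's mechanics and the *relative*
behaviour of detectors under controlled SNR, not clinical performance on
recorded sEMG.

## Classical baselines

Three standard detectors share the evaluation interface: a fixed threshold
on the rectified, 100 ms moving-average envelope; an adaptive threshold at
`mean + h * sd` of the initial 500 ms rest segment (h = 3 by default); and
a sliding statistic that standardizes the trailing 100 ms envelope mean
against the rest-segment statistics. Their thresholds are tuned on
validation trials by the same grid-search harness as the decision rule.
The centred envelope smoothing gives these detectors up to half a smoothing
window of look-ahead - a small advantage deliberately left with the
baselines.

## Scaled-down benchmark

The packaged study (`tests/testthat/helper-benchmark.R`) runs 8 subjects x
20 trials per noise tier (3 s trials, onsets 300-1000 ms, rises 300-1200
ms, 25% rest trials) under 2-fold subject-wise cross-validation. Each
noise tier is its own experiment: per fold and tier, the network trains on
three subjects (one more drives early stopping and threshold tuning,
capped at 15 epochs) and every detector is evaluated on the four held-out
subjects of that tier. Fitting per tier matters because trial-level
normalization gives each tier a different normalized rest level, so a
decision boundary learned at one tier is systematically misplaced at
another. These sizes are the package's desk-scale protocol choice; the
expectations checked are *directional* - the trained network's mean ODE
beats the tuned fixed threshold at the medium tier, and its ODE does not
improve as noise increases - rather than numeric reproductions, because
the original recordings are not publicly available.

The fixed-threshold baseline is structurally handicapped on trial-normalized
signals: the rest-level of a z-scored trial depends on the trial's
activation fraction, so one global threshold misfires on late-onset trials.
This is precisely the failure mode that motivates adaptive and learned
detectors, and the benchmark preserves it on purpose.

## Numerical choices and degenerate inputs

* Second-order-section filtering; biquad cascade verified against the
  analytic Butterworth magnitude (bilinear-prewarped) to within 1%.
* `ms` quantities must convert to whole samples; a non-integer conversion is
  an error rather than a silent rounding.
* Empty window sets (trial shorter than one window) warn and yield zero
  windows; stitching demands contiguous coverage and refuses gaps.
* Constant channels, non-binary targets, subject leakage, undefined SNR on
  rest trials and out-of-range decision thresholds all fail fast with typed
  conditions.
* The convolution forward/backward passes are compiled (RcppArmadillo) and
  are verified against scalar-loop oracles and numerical gradients
  (relative error below 1e-6) in the test suite.

## Known limitations

* The synthetic carrier is stationary Gaussian; real sEMG noise is not.
* Single onset per trial; offset (activation end) detection and multi-burst
  segmentation are out of scope.
* The causal filtering mode reports onsets delayed by the filter's group
  delay; no compensation is applied.
* Training on a CPU in R is adequate for the desk-scale studies here but
  not for datasets orders of magnitude larger.

## Reproducing the packaged results

`scripts/acceptance.R --seed <int> --out <path>` re-solves the architecture
calibration, instantiates the network and writes the measured trainable-
parameter total as JSON. The full directional benchmark runs inside the
test suite (`testthat::test_dir("tests/testthat")`), seeded and
deterministic.
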