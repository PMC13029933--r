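# slowonset

Detection of **slow muscle activation onsets** in multi-channel surface
EMG (sEMG).

## The problem

In rehabilitation training, assistive robotics and long-term monitoring,
muscle activation often begins gradually: the sEMG amplitude envelope rises
over hundreds of milliseconds with no abrupt burst, and the sustained level
sits only a few dB above resting noise. Classical onset detectors - fixed
thresholds, adaptive thresholds, sliding-window statistics on the rectified
envelope - either trigger late or false-trigger on noise in this regime.
`slowonset` implements a lightweight learned detector for slow onsets plus
everything needed to study it end to end: preprocessing, augmentation,
training, a stable decision rule, classical baselines, evaluation metrics,
subject-wise cross-validation and a synthetic slow-activation sEMG
generator with known ground truth.

## The method

A preprocessed window `X ∈ R^(C×T)` (band-passed 20-450 Hz with a 4th-order
Butterworth, per-channel z-scored over the whole trial, cut into 250 ms
windows with 50 ms stride) passes through:

1. **Shallow temporal encoder** - a causal width-5 1D convolution,
   `F_{k,t} = Σ_c Σ_{τ=0}^{K-1} W_{k,c,τ} X_{c,t-τ} + b_k`, plus a 1×1
   channel map (C′ = 28 channels).
2. **Neighbourhood-constrained temporal attention** - per time step the
   context `Z_t = Concat(F_{:,t-k:t+k}, F_{:,t})` (radius k = 2) is mapped
   by two shared width-3 convolutions (32 → 16 channels, ReLU between) and
   a 1×1 projection to a sigmoid weight `α_t ∈ [0,1]`, and
   `F̃_{:,t} = α_t · F_{:,t}`. Cost is linear in T.
3. **Gated stable decision stack** - three units computing
   `S_t = tanh(U_t) · sigmoid(V_t)` from parallel width-3 convolutions,
   an adaptive low-pass that suppresses isolated spikes.
4. **Confidence head** - 1×1 → ReLU → 1×1 → sigmoid, yielding a per-sample
   slow-activation confidence `y_t ∈ [0,1]`.

The assembled network has **24,580 trainable parameters** (the free widths
are solved by `calibrate_net_widths()` against that budget). Per-window
traces are stitched to a trial-level curve and the onset is declared at the
first time the **trailing 100 ms mean of `y` strictly exceeds θ = 0.75**
(both tuned by grid search on validation subjects, then frozen). Training
is SGD (batch 128, lr 0.001, Nesterov 0.9, weight decay 1e-4) with a
plateau schedule and early stopping, under strict subject-wise splits.

Metrics: onset detection error `ODE = mean |t_pred − t_gt|`, detection
delay `mean max(0, t_pred − t_gt)`, window-level false positive rate
`N_fp/(N_fp+N_tn)`, real-time factor, and window classification
accuracy/precision/recall.

## Worked example

```r
library(slowonset)

## a synthetic 8-subject study at the medium noise tier (10 dB)
cfg <- sim_config(n_subjects = 2, trials_per_subject = 4,
                  duration_ms = 3000,
                  ramp_start_range_ms = c(300, 1000),
                  ramp_duration_range_ms = c(300, 1200),
                  noise_tier = "medium", seed = 42)
ds <- simulate_dataset(cfg)
ds[[2]]
#> <semg_trial> subject S01 | 6 ch x 3000 samples @ 1000 Hz | onset 327.3 ms | tier medium
realized_snr_db(ds[[2]])
#> [1] 9.596437

## preprocessing: 4th-order 20-450 Hz Butterworth, trial z-score, windows
ws <- preprocess_trial(ds[[2]], filter_spec(), L_ms = 250, S_ms = 50)
dim(ws$windows)                    # 56 windows x 6 channels x 250 samples
#> [1]  56   6 250
sum(ws$labels)                     # windows overlapping activation > 50%
#> [1] 51

## the network: calibrated to the 24,580-parameter budget
net <- init_net(net_config())
net
#> <onset_net> 13 layers, 24580 trainable parameters

## classical baseline on the same trial
tr <- ds[[2]]
tr$signal <- normalize_trial(bandpass(tr$signal, tr$fs, filter_spec()))
detect_with_baseline(tr, "adaptive", baseline_config())$onset_ms
#> [1] 500
```

The simulated trial's annotated onset is at 327.3 ms (and the realized
plateau-to-rest SNR is 9.6 dB against the 10 dB target); the adaptive
threshold baseline reports 500 ms, i.e. it needs ~170 ms of envelope
growth before it clears the rest-statistics threshold — the characteristic
lag of threshold detectors on slow onsets that the learned detector is
designed to shrink. Training and the full comparison run inside the
benchmark harness (`run_benchmark()`, or `run_cross_validation()` for a
single dataset).

## Command-line interface

A thin Rscript CLI wraps the package functions:

```sh
Rscript inst/cli/slowonset.R simulate  --config cfg.yaml --out data/
Rscript inst/cli/slowonset.R detect    --in data/ --method adaptive --out det/
Rscript inst/cli/slowonset.R benchmark --config cfg.yaml --out bench/
Rscript inst/cli/slowonset.R calibrate-params --target 24580 --out calib/
```

Every run writes its fully resolved YAML configuration next to its outputs.

## Scope

Synthetic and imported trials (TSV + JSON sidecar + CSV manifest container);
single onset per trial; offset detection, learned comparison models
(SVM/CNN/LSTM/Transformer) and physiological motor-unit simulation are out
of scope. See the methods vignette
(`vignettes/slow-onset-detection.Rmd`) for model assumptions, parameter
meanings, numerical choices and known limitations.
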