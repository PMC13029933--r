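#' Signal-to-noise tiers for synthetic trials
#'
#' Plateau-to-rest RMS ratios (dB) defining the low/medium/high noise tiers
#' used by the robustness experiments. The tier names refer to the *noise*
#' level, so the low-noise tier has the highest SNR.
#'
#' @format named numeric vector of length 3 (dB).
#' @export
snr_tier_db <- c(low = 16, medium = 10, high = 4)

#' Configuration of the synthetic slow-activation sEMG generator
#'
#' The generator emulates the defining traits of slow activation recordings:
#' band-limited (20-450 Hz) stochastic carrier, a slow smoothstep amplitude
#' ramp lasting hundreds of milliseconds with no abrupt burst, low SNR tiers,
#' per-subject amplitude scale (lognormal) and small per-channel onset jitter.
#' Activation, once established, is sustained to the end of the trial.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials generated per subject.
#' @param n_channels sEMG channels per trial.
#' @param fs sampling rate in Hz.
#' @param duration_ms trial length (ms).
#' @param ramp_start_range_ms interval the onset time t0 is drawn from (ms).
#' @param ramp_duration_range_ms interval the envelope rise time is drawn
#'   from (ms); the default 300-1500 ms is the "slow" regime.
#' @param noise_tier one of `"low"`, `"medium"`, `"high"`; sets `snr_db` from
#'   [snr_tier_db] unless `snr_db` is given explicitly.
#' @param snr_db target plateau-to-baseline RMS ratio in dB.
#' @param subject_gain_sd lognormal spread (sdlog) of the per-subject
#'   amplitude scale.
#' @param channel_jitter_ms maximal per-channel onset offset (ms); the
#'   earliest channel always starts exactly at t0.
#' @param rest_trial_fraction fraction of activation-free trials per subject
#'   (the first `round(fraction * trials_per_subject)` trial indices).
#' @param baseline_gain RMS of the resting signal (arbitrary units).
#' @param seed global integer seed; per-subject/per-trial substreams are
#'   derived with [substream_seed()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 5,
                       trials_per_subject = 10,
                       n_channels = 6,
                       fs = 1000,
                       duration_ms = 4000,
                       ramp_start_range_ms = c(300, 1200),
                       ramp_duration_range_ms = c(300, 1500),
                       noise_tier = "medium",
                       snr_db = NULL,
                       subject_gain_sd = 0.3,
                       channel_jitter_ms = 30,
                       rest_trial_fraction = 0.25,
                       baseline_gain = 1,
                       seed = 42) {
  noise_tier <- match.arg(noise_tier, names(snr_tier_db))
  snr_db <- snr_db %||% unname(snr_tier_db[noise_tier])
  cfg <- structure(list(
    n_subjects = n_subjects, trials_per_subject = trials_per_subject,
    n_channels = n_channels, fs = fs, duration_ms = duration_ms,
    ramp_start_range_ms = ramp_start_range_ms,
    ramp_duration_range_ms = ramp_duration_range_ms,
    noise_tier = noise_tier, snr_db = snr_db,
    subject_gain_sd = subject_gain_sd, channel_jitter_ms = channel_jitter_ms,
    rest_trial_fraction = rest_trial_fraction,
    baseline_gain = baseline_gain, seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is_count(cfg$n_subjects), is_count(cfg$trials_per_subject),
            is_count(cfg$n_channels), cfg$fs > 0, cfg$duration_ms > 0)
  if (cfg$ramp_duration_range_ms[1] <= 0) {
    abort("ramp_duration_range_ms lower bound must be > 0", "slowonset_bad_config")
  }
  if (!is.finite(cfg$snr_db)) abort("snr_db must be finite", "slowonset_bad_config")
  if (cfg$rest_trial_fraction < 0 || cfg$rest_trial_fraction > 1) {
    abort("rest_trial_fraction must lie in [0, 1]", "slowonset_bad_config")
  }
  ## every drawable (t0, rise) must leave a plateau of >= 250 ms inside the trial
  worst <- max(cfg$ramp_start_range_ms) + cfg$channel_jitter_ms +
    max(cfg$ramp_duration_range_ms) + 250
  if (worst > cfg$duration_ms) {
    abort(sprintf(
      "envelope does not fit: t0 + jitter + rise + 250 ms plateau may reach %g ms in a %g ms trial",
      worst, cfg$duration_ms), "slowonset_bad_config")
  }
  cfg
}

#' Smoothstep activation envelope
#'
#' Amplitude envelope used by the simulator: identically zero before `t0`
#' (so the generative ground truth is exact), a cubic smoothstep
#' `3u^2 - 2u^3` over the rise, a flat plateau at 1, and a mirrored
#' smoothstep release. The curve is continuously differentiable and monotone
#' on each segment.
#'
#' @param t time grid in ms (non-decreasing).
#' @param t0 ramp start (ms).
#' @param rise_ms rise duration (ms), > 0.
#' @param plateau_ms plateau duration (ms); `Inf` gives a sustained
#'   activation with no release.
#' @return numeric vector in `[0, 1]`, same length as `t`.
#' @export
#' @examples
#' tt <- seq(0, 2000, by = 1)
#' env <- activation_envelope(tt, t0 = 400, rise_ms = 600, plateau_ms = 500)
activation_envelope <- function(t, t0, rise_ms, plateau_ms = Inf) {
  if (rise_ms <= 0) abort("rise_ms must be > 0", "slowonset_bad_input")
  if (is.unsorted(t)) abort("time grid must be non-decreasing", "slowonset_bad_input")
  smoothstep <- function(u) {
    u <- pmin(pmax(u, 0), 1)
    u * u * (3 - 2 * u)
  }
  env <- smoothstep((t - t0) / rise_ms)
  if (is.finite(plateau_ms)) {
    rel_start <- t0 + rise_ms + plateau_ms
    env <- pmin(env, 1 - smoothstep((t - rel_start) / rise_ms))
  }
  env
}

## unit-RMS band-limited Gaussian carrier, one channel
shaped_carrier <- function(n, fs, low_hz = 20, high_hz = 450) {
  x <- rnorm(n)
  spec <- filter_spec(low_hz = low_hz, high_hz = high_hz, mode = "causal")
  y <- bandpass(matrix(x, nrow = 1), fs, spec)[1, ]
  y / sqrt(mean(y^2))
}

#' Simulate one slow-activation sEMG trial
#'
#' The per-channel signal is a unit-RMS band-limited (20-450 Hz) Gaussian
#' carrier, amplitude-modulated as
#' `gain * (1 + (10^(snr_db/20) - 1) * envelope(t))`, so the plateau-to-rest
#' RMS ratio hits the configured SNR. Each channel's ramp start is jittered
#' by up to `channel_jitter_ms`; the earliest channel starts exactly at the
#' drawn t0, which is recorded as `onset_ms`. Activation is sustained to the
#' end of the trial (`offset_ms = duration_ms`). Rest trials carry no
#' envelope and `onset_ms = NA`.
#'
#' @param cfg a [sim_config()].
#' @param subject_id subject identifier string.
#' @param seed integer seed for this trial's substream.
#' @param subject_gain per-subject amplitude scale; default 1.
#' @param rest logical; generate an activation-free trial.
#' @return an object of class `semg_trial` with fields `subject_id`,
#'   `action_label`, `fs`, `signal` (channels x samples), `onset_ms`,
#'   `offset_ms`, `noise_tier`, `provenance`.
#' @export
simulate_trial <- function(cfg, subject_id = "S01", seed = cfg$seed,
                           subject_gain = 1, rest = FALSE) {
  validate_sim_config(cfg)
  set.seed(seed)
  n <- ms_to_samples(cfg$duration_ms, cfg$fs)
  t_ms <- sample_to_ms(seq_len(n), cfg$fs)
  gain <- cfg$baseline_gain * subject_gain
  act_gain <- 10^(cfg$snr_db / 20) - 1

  if (!rest) {
    t0 <- runif(1, cfg$ramp_start_range_ms[1], cfg$ramp_start_range_ms[2])
    rise <- runif(1, cfg$ramp_duration_range_ms[1], cfg$ramp_duration_range_ms[2])
    jit <- runif(cfg$n_channels, 0, cfg$channel_jitter_ms)
    jit <- jit - min(jit)   # earliest channel ramps exactly at t0
  }

  sig <- matrix(0, nrow = cfg$n_channels, ncol = n)
  for (ch in seq_len(cfg$n_channels)) {
    carrier <- shaped_carrier(n, cfg$fs)
    env <- if (rest) 0 else activation_envelope(t_ms, t0 + jit[ch], rise)
    sig[ch, ] <- carrier * gain * (1 + act_gain * env)
  }

  new_trial(
    subject_id = subject_id, action_label = if (rest) "rest" else "slow_activation",
    fs = cfg$fs, signal = sig,
    onset_ms = if (rest) NA_real_ else t0,
    offset_ms = if (rest) NA_real_ else cfg$duration_ms,
    noise_tier = cfg$noise_tier, provenance = "synthetic"
  )
}

#' Construct a trial object
#'
#' @param subject_id,action_label,fs,signal,onset_ms,offset_ms,noise_tier,provenance
#'   trial fields; `signal` is a channels x samples matrix, `onset_ms` /
#'   `offset_ms` are ms from trial start or `NA` for rest trials.
#' @return an object of class `semg_trial`.
#' @export
new_trial <- function(subject_id, action_label = "unknown", fs, signal,
                      onset_ms = NA_real_, offset_ms = NA_real_,
                      noise_tier = "medium", provenance = "imported") {
  check_signal_matrix(signal)
  dur <- ncol(signal) / fs * 1000
  if (!is.na(onset_ms)) {
    if (!(onset_ms >= 0 && onset_ms < offset_ms && offset_ms <= dur + 1e-9)) {
      abort("activation interval must satisfy 0 <= onset < offset <= duration",
            "slowonset_bad_input")
    }
  }
  structure(list(
    subject_id = subject_id, action_label = action_label, fs = fs,
    signal = signal, onset_ms = onset_ms, offset_ms = offset_ms,
    noise_tier = noise_tier, provenance = provenance
  ), class = "semg_trial")
}

#' @export
print.semg_trial <- function(x, ...) {
  cat(sprintf("<semg_trial> subject %s | %d ch x %d samples @ %g Hz | onset %s ms | tier %s\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$fs,
              if (is.na(x$onset_ms)) "none" else format(round(x$onset_ms, 1)),
              x$noise_tier))
  invisible(x)
}

trial_duration_ms <- function(trial) ncol(trial$signal) / trial$fs * 1000

#' Realized signal-to-noise ratio of a simulated trial
#'
#' `20 * log10(RMS over the activation plateau / RMS over the pre-onset
#' rest)`, pooling channels. The plateau segment is the final 250 ms of the
#' activation interval.
#'
#' @param trial a `semg_trial` with a present onset.
#' @return SNR in dB.
#' @export
realized_snr_db <- function(trial) {
  if (is.na(trial$onset_ms)) {
    abort("SNR is undefined for a trial without an onset", "slowonset_undefined_snr")
  }
  fs <- trial$fs
  n <- ncol(trial$signal)
  rest_end <- floor(trial$onset_ms * fs / 1000)
  p_hi <- min(n, round(trial$offset_ms * fs / 1000))
  p_lo <- p_hi - ms_to_samples(250, fs) + 1
  if (rest_end < 1 || p_lo <= rest_end) {
    abort("trial lacks a usable rest or plateau segment", "slowonset_undefined_snr")
  }
  rms <- function(x) sqrt(mean(x^2))
  20 * log10(rms(trial$signal[, p_lo:p_hi]) / rms(trial$signal[, seq_len(rest_end)]))
}

#' Simulate a dataset of slow-activation trials grouped by subject
#'
#' Per-subject amplitude scales are drawn once per subject from a lognormal
#' with `sdlog = subject_gain_sd`; each trial then uses its own seeded
#' substream, so regeneration under the same config and seed is bit-exact.
#' Within each subject, the first `round(rest_trial_fraction *
#' trials_per_subject)` trial indices are rest trials.
#'
#' @param cfg a [sim_config()].
#' @return a list of `semg_trial` objects (class `semg_dataset`), in
#'   subject-major order.
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_subjects = 2, trials_per_subject = 3,
#'                                   duration_ms = 2000,
#'                                   ramp_start_range_ms = c(300, 500),
#'                                   ramp_duration_range_ms = c(300, 600)))
#' length(ds)
simulate_dataset <- function(cfg) {
  validate_sim_config(cfg)
  n_rest <- round(cfg$rest_trial_fraction * cfg$trials_per_subject)
  trials <- vector("list", cfg$n_subjects * cfg$trials_per_subject)
  idx <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(substream_seed(cfg$seed, s))
    gain <- rlnorm(1, meanlog = 0, sdlog = cfg$subject_gain_sd)
    for (tr in seq_len(cfg$trials_per_subject)) {
      idx <- idx + 1L
      trials[[idx]] <- simulate_trial(
        cfg, subject_id = sid,
        seed = substream_seed(cfg$seed, s, tr),
        subject_gain = gain, rest = tr <= n_rest
      )
    }
  }
  structure(trials, class = c("semg_dataset", "list"))
}

#' Subject ids of a dataset
#' @param dataset a list of `semg_trial` objects.
#' @return character vector, one entry per trial.
#' @export
dataset_subjects <- function(dataset) {
  vapply(dataset, function(tr) tr$subject_id, character(1))
}
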