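#' Baseline detector configuration
#'
#' Parameters of the three classical onset detectors: fixed threshold on the
#' smoothed envelope, adaptive threshold from rest-segment statistics
#' (mean + h * sd), and a sliding-window standardized statistic.
#'
#' @param envelope_smooth_ms moving-average length of the envelope (ms).
#' @param fixed_thr threshold on the envelope (fixed-threshold method).
#' @param baseline_ms initial rest segment used for adaptive statistics (ms).
#' @param h adaptive multiplier (threshold = mean + h * sd).
#' @param stat_window_ms trailing window of the sliding statistic (ms).
#' @param stat_thr threshold on the standardized sliding statistic.
#' @return an object of class `baseline_config`.
#' @export
baseline_config <- function(envelope_smooth_ms = 100, fixed_thr = 1,
                            baseline_ms = 500, h = 3,
                            stat_window_ms = 100, stat_thr = 3) {
  if (h <= 0) abort("adaptive multiplier h must be > 0", "slowonset_bad_config")
  structure(list(envelope_smooth_ms = envelope_smooth_ms, fixed_thr = fixed_thr,
                 baseline_ms = baseline_ms, h = h,
                 stat_window_ms = stat_window_ms, stat_thr = stat_thr),
            class = "baseline_config")
}

#' Rectified, smoothed amplitude envelope
#'
#' Full-wave rectification, mean across channels, then a centred moving
#' average of `smooth_ms` (window shrinks symmetrically at the edges). This
#' is the standard front end of classical threshold detectors; detections
#' derived from it carry up to half the smoothing window of look-ahead.
#'
#' @param signal channels x samples matrix (already filtered).
#' @param fs sampling rate (Hz).
#' @param smooth_ms moving-average length (ms).
#' @return non-negative numeric vector, one value per sample.
#' @export
semg_envelope <- function(signal, fs, smooth_ms = 100) {
  check_signal_matrix(signal)
  r <- colMeans(abs(signal))
  w <- max(1L, ms_to_samples(smooth_ms, fs, "smoothing window"))
  half <- w %/% 2
  n <- length(r)
  cs <- cumsum(c(0, r))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

first_crossing_ms <- function(x, fs, thr, from = 1L) {
  idx <- which(x[from:length(x)] > thr)[1]
  if (is.na(idx)) NA_real_ else sample_to_ms(from + idx - 1L, fs)
}

#' Fixed-threshold onset detector
#'
#' Earliest sample whose envelope strictly exceeds a fixed threshold.
#'
#' @param env envelope from [semg_envelope()].
#' @param fs sampling rate (Hz).
#' @param thr positive threshold.
#' @return onset time (ms) or `NA`.
#' @export
fixed_threshold_onset <- function(env, fs, thr) {
  if (thr <= 0) abort("threshold must be > 0", "slowonset_bad_config")
  first_crossing_ms(env, fs, thr)
}

#' Adaptive-threshold onset detector
#'
#' The threshold is `mean + h * sd` of the envelope over the initial
#' `baseline_ms` rest segment; the onset is the earliest later sample
#' strictly above it.
#'
#' @param env envelope from [semg_envelope()].
#' @param fs sampling rate (Hz).
#' @param baseline_ms initial rest-segment length (ms).
#' @param h multiplier on the baseline standard deviation.
#' @return onset time (ms) or `NA`.
#' @export
adaptive_threshold_onset <- function(env, fs, baseline_ms = 500, h = 3) {
  nb <- ms_to_samples(baseline_ms, fs, "baseline segment")
  if (nb >= length(env)) {
    abort("trial shorter than the baseline segment", "slowonset_bad_input")
  }
  thr <- mean(env[seq_len(nb)]) + h * sd(env[seq_len(nb)])
  first_crossing_ms(env, fs, thr, from = nb + 1L)
}

#' Sliding-window statistical onset detector
#'
#' Standardizes the trailing `stat_window_ms` mean of the envelope against
#' the initial rest-segment statistics, `z(t) = (trailing mean - baseline
#' mean) / baseline sd`, and reports the earliest post-baseline sample with
#' `z > stat_thr`.
#'
#' @param signal channels x samples matrix (filtered).
#' @param fs sampling rate (Hz).
#' @param stat_window_ms trailing-window length (ms).
#' @param stat_thr threshold on z.
#' @param baseline_ms initial rest-segment length (ms).
#' @param smooth_ms envelope smoothing (ms).
#' @return onset time (ms) or `NA`.
#' @export
sliding_stat_onset <- function(signal, fs, stat_window_ms = 100, stat_thr = 3,
                               baseline_ms = 500, smooth_ms = 100) {
  env <- semg_envelope(signal, fs, smooth_ms)
  nb <- ms_to_samples(baseline_ms, fs, "baseline segment")
  if (nb >= length(env)) {
    abort("trial shorter than the baseline segment", "slowonset_bad_input")
  }
  mu <- mean(env[seq_len(nb)])
  sigma <- sd(env[seq_len(nb)])
  W <- max(1L, ms_to_samples(stat_window_ms, fs, "statistic window"))
  n <- length(env)
  cs <- cumsum(env)
  tm <- rep(NA_real_, n)
  tm[W:n] <- (cs[W:n] - c(0, cs[seq_len(n - W)])) / W
  z <- (tm - mu) / sigma
  z[seq_len(max(nb, W - 1L))] <- NA_real_
  idx <- which(!is.na(z) & z > stat_thr)[1]
  if (is.na(idx)) NA_real_ else sample_to_ms(idx, fs)
}

#' Tune a baseline detector's threshold on validation trials
#'
#' The same grid-search harness as the learned detector's decision rule:
#' thresholds are parameterized as `baseline mean + h * baseline sd` of the
#' pooled validation rest-segment envelope, `h` over a grid; the mean onset
#' detection error is minimized with the rest-trial false-trigger rate as
#' first tie-break and the smaller threshold last.
#'
#' @param trials list of preprocessed (filtered, normalized) `semg_trial`s
#'   with ground-truth onsets (`NA` marks rest trials).
#' @param method one of `"fixed"`, `"adaptive"`, `"sliding"`.
#' @param cfg a [baseline_config()] (geometry parameters are taken from it).
#' @param h_grid candidate multipliers.
#' @return the tuned `baseline_config`.
#' @export
tune_baseline <- function(trials, method = c("fixed", "adaptive", "sliding"),
                          cfg = baseline_config(),
                          h_grid = seq(0.5, 10, by = 0.5)) {
  method <- match.arg(method)
  if (!length(trials)) abort("empty validation set", "slowonset_bad_input")
  onsets <- vapply(trials, function(tr) tr$onset_ms, numeric(1))
  envs <- lapply(trials, function(tr) semg_envelope(tr$signal, tr$fs, cfg$envelope_smooth_ms))
  nb <- function(tr) ms_to_samples(cfg$baseline_ms, tr$fs)
  pooled <- unlist(lapply(seq_along(trials), function(i) envs[[i]][seq_len(nb(trials[[i]]))]))
  mu <- mean(pooled); sigma <- sd(pooled)
  best <- cfg; best_key <- c(Inf, Inf, Inf)
  for (h in h_grid) {
    cand <- cfg
    cand$h <- h
    cand$stat_thr <- h
    cand$fixed_thr <- mu + h * sigma
    preds <- vapply(seq_along(trials), function(i) {
      detect_with_baseline(trials[[i]], method, cand, env = envs[[i]])$onset_ms
    }, numeric(1))
    act <- !is.na(onsets)
    errs <- abs(preds[act] - onsets[act])
    errs <- errs[!is.na(errs)]
    ode <- if (length(errs)) mean(errs) else Inf
    ftr <- if (any(!act)) mean(!is.na(preds[!act])) else 0
    key <- c(ode, ftr, h)
    if (compare_keys(key, best_key)) {
      best_key <- key
      best <- cand
    }
  }
  best
}

#' Run one baseline detector on a preprocessed trial
#'
#' @param trial a `semg_trial` whose signal is already filtered and
#'   normalized.
#' @param method one of `"fixed"`, `"adaptive"`, `"sliding"`.
#' @param cfg a [baseline_config()].
#' @param env optionally a precomputed envelope.
#' @return list with `onset_ms` (or `NA`) and `active`, a per-sample logical
#'   decision sequence used for window-level false-positive accounting.
#' @export
detect_with_baseline <- function(trial, method, cfg = baseline_config(), env = NULL) {
  fs <- trial$fs
  env <- env %||% semg_envelope(trial$signal, fs, cfg$envelope_smooth_ms)
  if (method == "fixed") {
    onset <- fixed_threshold_onset(env, fs, cfg$fixed_thr)
    active <- env > cfg$fixed_thr
  } else if (method == "adaptive") {
    nb <- ms_to_samples(cfg$baseline_ms, fs)
    thr <- mean(env[seq_len(nb)]) + cfg$h * sd(env[seq_len(nb)])
    onset <- first_crossing_ms(env, fs, thr, from = nb + 1L)
    active <- env > thr
    active[seq_len(nb)] <- FALSE
  } else if (method == "sliding") {
    onset <- sliding_stat_onset(trial$signal, fs, cfg$stat_window_ms,
                                cfg$stat_thr, cfg$baseline_ms,
                                cfg$envelope_smooth_ms)
    nb <- ms_to_samples(cfg$baseline_ms, fs)
    W <- max(1L, ms_to_samples(cfg$stat_window_ms, fs))
    n <- length(env)
    cs <- cumsum(env)
    tm <- rep(NA_real_, n)
    tm[W:n] <- (cs[W:n] - c(0, cs[seq_len(n - W)])) / W
    mu <- mean(env[seq_len(nb)]); sigma <- sd(env[seq_len(nb)])
    active <- !is.na(tm) & (tm - mu) / sigma > cfg$stat_thr
    active[seq_len(nb)] <- FALSE
  } else {
    abort(sprintf("unknown baseline method '%s'", method), "slowonset_bad_input")
  }
  list(onset_ms = onset, active = active)
}
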