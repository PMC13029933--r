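#' Band-pass filter specification
#'
#' A Butterworth band-pass of total order `order` (so `order/2` analog
#' prototype poles before the band-pass transform), realized as a cascade of
#' second-order sections: with the upper cutoff close to Nyquist at 1000 Hz
#' sampling, a single direct-form transfer function is numerically fragile.
#'
#' @param order total filter order (even; default 4).
#' @param low_hz lower cutoff (Hz).
#' @param high_hz upper cutoff (Hz); clamped to `0.45 * fs` at filter time
#'   when the sampling rate is too low (with a warning).
#' @param mode `"zero_phase"` (forward-backward, no group delay; the default
#'   so filter delay cannot bias onset labels) or `"causal"` (single pass,
#'   suitable for streaming).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 4, low_hz = 20, high_hz = 450,
                        mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order %% 2 != 0 || order < 2) {
    abort("band-pass order must be a positive even number", "slowonset_bad_config")
  }
  if (!(low_hz > 0 && low_hz < high_hz)) {
    abort("cutoffs must satisfy 0 < low_hz < high_hz", "slowonset_bad_config")
  }
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz, mode = mode),
            class = "filter_spec")
}

## Second-order-section design of the Butterworth band-pass.
## Poles come from signal::butter's denominator; each biquad gets one zero at
## z = +1 and one at z = -1 (the band-pass zeros), and the overall gain is
## split evenly across sections.
design_sos <- function(spec, fs) {
  if (fs <= 2 * spec$low_hz) {
    abort(sprintf("sampling rate %g Hz unusable: must exceed twice the %g Hz lower cutoff",
                  fs, spec$low_hz), "slowonset_bad_fs")
  }
  high <- spec$high_hz
  if (high > 0.45 * fs) {
    high <- 0.45 * fs
    warning(sprintf("upper cutoff clamped to %g Hz (0.45 * fs) at fs = %g Hz",
                    high, fs), call. = FALSE)
  }
  bf <- signal::butter(spec$order / 2, c(spec$low_hz, high) * 2 / fs, type = "pass")
  poles <- polyroot(rev(bf$a))
  poles <- poles[order(-Mod(poles), Arg(poles))]
  nsec <- spec$order / 2
  ## pair complex-conjugate poles: sort by modulus, take one of each conjugate
  ## pair in sequence
  used <- rep(FALSE, length(poles))
  pairs <- vector("list", nsec)
  k <- 0L
  for (i in seq_along(poles)) {
    if (used[i]) next
    j <- which(!used & seq_along(poles) != i &
                 abs(poles - Conj(poles[i])) < 1e-6)[1]
    if (is.na(j)) j <- which(!used & seq_along(poles) != i)[1]
    used[c(i, j)] <- TRUE
    k <- k + 1L
    pairs[[k]] <- c(poles[i], poles[j])
  }
  g <- abs(bf$b[1])^(1 / nsec) * sign(bf$b[1])
  lapply(pairs, function(p) {
    a <- Re(c(1, -(p[1] + p[2]), p[1] * p[2]))
    list(b = g * c(1, 0, -1), a = a)
  })
}

## Zero-phase filtering with odd-reflection padding at both ends, so the
## filter is warmed up before it meets real data: without it the startup
## transient leaks an artificial amplitude burst into the first tens of
## milliseconds of every trial, which any amplitude-sensitive detector will
## happily mistake for activity.
apply_sos <- function(x, sos, zero_phase, n_pad = 0) {
  n <- length(x)
  if (zero_phase && n_pad > 0) {
    n_pad <- min(n - 1L, n_pad)
    left <- 2 * x[1] - x[(n_pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - n_pad)]
    x <- c(left, x, right)
  }
  for (sec in sos) {
    flt <- signal::Arma(b = sec$b, a = sec$a)
    x <- if (zero_phase) signal::filtfilt(flt, x) else signal::filter(flt, x)
  }
  x <- as.numeric(x)
  if (zero_phase && n_pad > 0) x <- x[(n_pad + 1L):(n_pad + n)]
  x
}

#' Band-pass filter a multi-channel sEMG signal
#'
#' Filters each channel independently with the Butterworth band-pass
#' described by `spec`. Zero-phase mode runs the second-order-section cascade
#' forward and backward (squaring the magnitude response, no group delay);
#' causal mode runs a single forward pass and carries the filter's group
#' delay.
#'
#' @param signal channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param spec a [filter_spec()].
#' @return filtered matrix of the same shape.
#' @export
#' @examples
#' x <- matrix(rnorm(2 * 1000), nrow = 2)
#' y <- bandpass(x, fs = 1000, filter_spec())
bandpass <- function(signal, fs, spec = filter_spec()) {
  check_signal_matrix(signal)
  sos <- design_sos(spec, fs)
  zp <- spec$mode == "zero_phase"
  n_pad <- max(50L, round(3 * fs / spec$low_hz))   # covers the slowest pole
  out <- signal
  for (ch in seq_len(nrow(signal))) {
    out[ch, ] <- apply_sos(signal[ch, ], sos, zp, n_pad)
  }
  out
}

#' Trial-level z-score normalization
#'
#' Per channel, subtracts the whole-trial mean and divides by the whole-trial
#' standard deviation, so the model sees relative variation patterns rather
#' than subject-specific amplitude scales. Normalization is deliberately
#' global over the continuous trial, never window-local, to preserve the
#' macroscopic amplitude trend that defines a slow onset.
#'
#' @param filtered channels x samples matrix (typically the output of
#'   [bandpass()]).
#' @param sd_floor smallest admissible channel standard deviation.
#' @return normalized matrix, per-channel mean 0 and sd 1.
#' @export
normalize_trial <- function(filtered, sd_floor = 1e-9) {
  check_signal_matrix(filtered)
  mu <- rowMeans(filtered)
  sigma <- apply(filtered, 1, sd)
  bad <- which(sigma <= sd_floor)
  if (length(bad)) {
    abort(sprintf("channel %s is (near-)constant: sd below the %g floor",
                  paste(bad, collapse = ", "), sd_floor),
          "slowonset_degenerate_scale")
  }
  (filtered - mu) / sigma
}

#' Sliding-window segmentation
#'
#' Cuts the normalized trial into fixed-length half-open windows
#' `[k*S, k*S + L)`; the trailing partial window is dropped. Labels are left
#' unset (see [label_windows()]).
#'
#' @param normalized channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param L_ms window length (ms); must convert to whole samples.
#' @param S_ms stride (ms); must convert to whole samples.
#' @return an object of class `window_set` with fields `windows`
#'   (`n_windows x n_channels x L_samples` array), `start_ms`, `labels`
#'   (`NA` until labelled), `L_ms`, `S_ms`, `fs`.
#' @export
#' @examples
#' x <- matrix(rnorm(1000), nrow = 1)
#' ws <- segment(x, fs = 1000, L_ms = 250, S_ms = 50)
#' ws$start_ms
segment <- function(normalized, fs, L_ms = 250, S_ms = 50) {
  check_signal_matrix(normalized)
  L <- ms_to_samples(L_ms, fs, "window length")
  S <- ms_to_samples(S_ms, fs, "stride")
  n <- ncol(normalized)
  C <- nrow(normalized)
  if (n < L) {
    warning(sprintf("trial of %d samples shorter than the %d-sample window: empty window set", n, L),
            call. = FALSE)
    nw <- 0L
  } else {
    nw <- (n - L) %/% S + 1L
  }
  windows <- array(0, dim = c(nw, C, L))
  starts0 <- (seq_len(nw) - 1L) * S
  for (w in seq_len(nw)) {
    windows[w, , ] <- normalized[, (starts0[w] + 1):(starts0[w] + L), drop = FALSE]
  }
  structure(list(
    windows = windows, start_ms = starts0 / fs * 1000,
    labels = rep(NA_integer_, nw), L_ms = L_ms, S_ms = S_ms, fs = fs
  ), class = "window_set")
}

#' Label windows by majority overlap with the activation interval
#'
#' A window `[start, start + L)` is labelled active (1) iff its overlap with
#' the activation interval `[onset, offset)` strictly exceeds half the window
#' length; a missing interval labels every window 0. The strict inequality
#' means an exactly-half overlap is a rest window.
#'
#' @param ws a [segment()] result.
#' @param onset_ms,offset_ms activation interval in ms, or `NA` for a rest
#'   trial.
#' @return the `window_set` with binary `labels` filled in.
#' @export
label_windows <- function(ws, onset_ms, offset_ms) {
  nw <- length(ws$start_ms)
  if (is.null(onset_ms) || is.na(onset_ms)) {
    ws$labels <- rep(0L, nw)
    return(ws)
  }
  starts <- ws$start_ms
  ends <- starts + ws$L_ms
  overlap <- pmax(0, pmin(ends, offset_ms) - pmax(starts, onset_ms))
  ws$labels <- as.integer(overlap > ws$L_ms / 2)
  ws
}

#' Per-sample activity targets for a window set
#'
#' For each window, the binary indicator of the activation interval sampled
#' on the window's time grid; these per-sample targets drive the
#' cross-entropy training loss, while the window-level labels of
#' [label_windows()] are used for bookkeeping metrics only.
#'
#' @param ws a [segment()] result.
#' @param onset_ms,offset_ms activation interval (ms), `NA` for rest.
#' @return an `L_samples x n_windows` 0/1 matrix.
#' @export
window_targets <- function(ws, onset_ms, offset_ms) {
  L <- dim(ws$windows)[3]
  nw <- length(ws$start_ms)
  out <- matrix(0, nrow = L, ncol = nw)
  if (is.null(onset_ms) || is.na(onset_ms)) return(out)
  for (w in seq_len(nw)) {
    t_ms <- ws$start_ms[w] + (0:(L - 1)) / ws$fs * 1000
    out[, w] <- as.numeric(t_ms >= onset_ms & t_ms < offset_ms)
  }
  out
}

#' Full preprocessing chain for one trial
#'
#' [bandpass()] then [normalize_trial()] then [segment()] and
#' [label_windows()].
#'
#' @param trial a `semg_trial`.
#' @param spec a [filter_spec()].
#' @param L_ms,S_ms window length and stride (ms).
#' @return a labelled `window_set`.
#' @export
preprocess_trial <- function(trial, spec = filter_spec(), L_ms = 250, S_ms = 50) {
  x <- normalize_trial(bandpass(trial$signal, trial$fs, spec))
  ws <- segment(x, trial$fs, L_ms = L_ms, S_ms = S_ms)
  label_windows(ws, trial$onset_ms, trial$offset_ms)
}
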