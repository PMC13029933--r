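#' Decision-rule configuration
#'
#' The continuity criterion declares activation at time `t` when the mean
#' confidence over the trailing window of `omega_ms` strictly exceeds
#' `theta`. Both parameters are tuned once on validation data
#' ([tune_decision()]) and then kept fixed across subjects.
#'
#' @param theta stable decision threshold in `[0, 1]`.
#' @param omega_ms trailing-window length (ms).
#' @param theta_grid,omega_grid_ms grids for [tune_decision()].
#' @return an object of class `decision_config`.
#' @export
decision_config <- function(theta = 0.75, omega_ms = 100,
                            theta_grid = seq(0.5, 0.9, by = 0.05),
                            omega_grid_ms = c(50, 100, 150, 200)) {
  if (theta < 0 || theta > 1) {
    abort("`decision.theta` must lie in [0, 1]", "slowonset_bad_config")
  }
  if (omega_ms <= 0) abort("`decision.omega_ms` must be positive", "slowonset_bad_config")
  structure(list(theta = theta, omega_ms = omega_ms,
                 theta_grid = theta_grid, omega_grid_ms = omega_grid_ms),
            class = "decision_config")
}

#' Construct a confidence trace
#'
#' @param y per-time-step confidence values in `[0, 1]`.
#' @param fs sampling rate (Hz).
#' @param start_ms time of the first sample (ms from trial start).
#' @return an object of class `confidence_trace`.
#' @export
confidence_trace <- function(y, fs, start_ms = 0) {
  if (any(y < -1e-9 | y > 1 + 1e-9)) {
    abort("confidence values must lie in [0, 1]", "slowonset_bad_input")
  }
  structure(list(y = as.numeric(y), fs = fs, start_ms = start_ms),
            class = "confidence_trace")
}

#' Stitch per-window confidence traces into a trial-level trace
#'
#' Each trial sample's confidence is the arithmetic mean of all window
#' traces covering it. Windows must cover the trial contiguously from the
#' first sample; an interior gap is an error. Samples after the last window
#' end (a dropped trailing partial window) are not part of the stitched
#' trace.
#'
#' @param traces list of numeric per-window confidence vectors (all length
#'   L).
#' @param start_ms numeric vector of window start times (ms).
#' @param fs sampling rate (Hz).
#' @return a [confidence_trace()] starting at 0 ms.
#' @export
stitch <- function(traces, start_ms, fs) {
  if (!length(traces)) abort("no traces to stitch", "slowonset_coverage_error")
  L <- length(traces[[1]])
  starts <- ms_to_samples(start_ms, fs, "window start") + 1L
  n <- max(starts) + L - 1L
  acc <- numeric(n)
  cov <- numeric(n)
  for (i in seq_along(traces)) {
    idx <- starts[i]:(starts[i] + L - 1L)
    acc[idx] <- acc[idx] + traces[[i]]
    cov[idx] <- cov[idx] + 1
  }
  if (any(cov == 0)) {
    abort("windows do not cover the trial contiguously", "slowonset_coverage_error")
  }
  confidence_trace(acc / cov, fs = fs, start_ms = 0)
}

#' Trailing-window continuity decision
#'
#' Position `t` is flagged active iff the mean confidence over the trailing
#' window of `W` samples ending at `t` is strictly greater than `theta`.
#' Positions with an incomplete trailing window (`t < W`) are never flagged,
#' so an isolated confidence spike cannot trigger a detection.
#'
#' @param trace a [confidence_trace()].
#' @param cfg a [decision_config()].
#' @return logical vector, same length as the trace.
#' @export
continuity_decision <- function(trace, cfg = decision_config()) {
  y <- trace$y
  W <- max(1L, ms_to_samples(cfg$omega_ms, trace$fs, "decision window"))
  n <- length(y)
  if (W > n) abort("decision window longer than the trace", "slowonset_bad_input")
  cs <- cumsum(y)
  means <- (cs[W:n] - c(0, cs[seq_len(n - W)])) / W
  ## strict inequality with a guard against accumulated floating-point fuzz:
  ## a window mean exactly at theta must not trigger
  c(rep(FALSE, W - 1L), means > cfg$theta + 1e-9)
}

#' Detect the activation onset from a confidence trace
#'
#' The reported onset is the trigger time: the earliest position where the
#' continuity criterion holds. No back-correction is applied, so the
#' detection delay metric measures exactly this decision lag.
#'
#' @param trace a [confidence_trace()].
#' @param cfg a [decision_config()].
#' @return an `onset_prediction`: list with `onset_ms` (`NA` when the
#'   criterion never holds), `trace` and `config`.
#' @export
detect_onset <- function(trace, cfg = decision_config()) {
  dec <- continuity_decision(trace, cfg)
  hit <- which(dec)[1]
  onset_ms <- if (is.na(hit)) NA_real_ else trace$start_ms + sample_to_ms(hit, trace$fs)
  structure(list(onset_ms = onset_ms, trace = trace, config = cfg),
            class = "onset_prediction")
}

## window-level false-positive flags of a stitched decision sequence:
## a rest window is a false positive iff any of its samples is flagged
window_fp_flags <- function(decision, fs, start_ms, L_ms) {
  L <- ms_to_samples(L_ms, fs)
  starts <- ms_to_samples(start_ms, fs, "window start") + 1L
  vapply(starts, function(s) {
    idx <- s:min(length(decision), s + L - 1L)
    any(decision[idx])
  }, logical(1))
}

#' Grid-search the decision threshold and window on validation trials
#'
#' Exhaustive search over `theta_grid x omega_grid_ms`. For every candidate,
#' the mean onset detection error over validation activation trials is
#' computed (candidates detecting nothing score infinite); ties are broken
#' by lower rest-window false positive rate, then by smaller theta, then by
#' smaller omega. The returned configuration is frozen for testing.
#'
#' @param traces list of [confidence_trace()], one per validation trial.
#' @param onsets_ms numeric vector of ground-truth onsets (`NA` for rest
#'   trials); rest trials must be present so the false-positive tie-break is
#'   defined.
#' @param cfg a [decision_config()] supplying the grids.
#' @param L_ms,S_ms window geometry used for the rest-window FPR.
#' @return the tuned `decision_config`.
#' @export
tune_decision <- function(traces, onsets_ms, cfg = decision_config(),
                          L_ms = 250, S_ms = 50) {
  if (!length(traces)) abort("empty validation set", "slowonset_bad_input")
  act <- which(!is.na(onsets_ms))
  rest <- which(is.na(onsets_ms))
  best <- NULL
  best_key <- c(Inf, Inf, Inf, Inf)
  for (th in cfg$theta_grid) for (om in cfg$omega_grid_ms) {
    cand <- decision_config(theta = th, omega_ms = om,
                            theta_grid = cfg$theta_grid,
                            omega_grid_ms = cfg$omega_grid_ms)
    errs <- c()
    for (i in act) {
      pred <- detect_onset(traces[[i]], cand)
      if (!is.na(pred$onset_ms)) errs <- c(errs, abs(pred$onset_ms - onsets_ms[i]))
    }
    ode <- if (length(errs)) mean(errs) else Inf
    fpr <- 0
    if (length(rest)) {
      flags <- unlist(lapply(rest, function(i) {
        dec <- continuity_decision(traces[[i]], cand)
        tr_ms <- length(traces[[i]]$y) / traces[[i]]$fs * 1000
        nw <- max(0L, (ms_to_samples(tr_ms, traces[[i]]$fs) -
                         ms_to_samples(L_ms, traces[[i]]$fs)) %/%
                    ms_to_samples(S_ms, traces[[i]]$fs) + 1L)
        if (nw < 1) return(logical(0))
        window_fp_flags(dec, traces[[i]]$fs,
                        (seq_len(nw) - 1L) * S_ms, L_ms)
      }))
      fpr <- if (length(flags)) mean(flags) else 0
    }
    key <- c(ode, fpr, th, om)
    if (compare_keys(key, best_key)) {
      best_key <- key
      best <- cand
    }
  }
  best
}

## lexicographic "strictly better" with tolerance on the metric entries
compare_keys <- function(a, b, tol = 1e-12) {
  for (i in seq_along(a)) {
    if (is.infinite(a[i]) && is.infinite(b[i])) next
    if (a[i] < b[i] - tol) return(TRUE)
    if (a[i] > b[i] + tol) return(FALSE)
  }
  FALSE
}
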