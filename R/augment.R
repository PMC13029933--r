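#' Augmentation specification
#'
#' Two lightweight, physically motivated perturbations are used at training
#' time only: random amplitude scaling (electrode contact / fatigue
#' variability) and random temporal scaling (faster or slower activation
#' rhythms) with the onset labels scaled by the exact same factor. Factors
#' are drawn uniformly from their ranges.
#'
#' @param alpha_range closed interval for the amplitude factor; must contain 1.
#' @param beta_range closed interval for the temporal factor; must contain 1.
#' @param apply_probability per-sample probability that each augmentation
#'   fires.
#' @return an object of class `augment_spec`.
#' @export
augment_spec <- function(alpha_range = c(0.8, 1.2),
                         beta_range = c(0.8, 1.25),
                         apply_probability = 0.5) {
  for (r in list(alpha_range, beta_range)) {
    if (!(length(r) == 2 && r[1] > 0 && r[1] <= 1 && r[2] >= 1)) {
      abort("augmentation ranges must be positive intervals containing 1",
            "slowonset_bad_config")
    }
  }
  if (apply_probability < 0 || apply_probability > 1) {
    abort("apply_probability must lie in [0, 1]", "slowonset_bad_config")
  }
  structure(list(alpha_range = alpha_range, beta_range = beta_range,
                 apply_probability = apply_probability),
            class = "augment_spec")
}

#' Draw an amplitude factor
#' @param spec an [augment_spec()].
#' @param n number of draws.
#' @return uniform draws from `alpha_range`.
#' @export
draw_alpha <- function(spec, n = 1) runif(n, spec$alpha_range[1], spec$alpha_range[2])

#' Draw a temporal factor
#' @param spec an [augment_spec()].
#' @param n number of draws.
#' @return uniform draws from `beta_range`.
#' @export
draw_beta <- function(spec, n = 1) runif(n, spec$beta_range[1], spec$beta_range[2])

#' Amplitude perturbation
#'
#' Multiplies every sample of a segment (or matrix of segments) by a single
#' positive factor; labels and times are untouched.
#'
#' @param segment numeric vector, matrix or array.
#' @param alpha positive scaling factor.
#' @return the scaled segment.
#' @export
amplitude_perturb <- function(segment, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0) {
    abort("amplitude factor must be a single positive number", "slowonset_bad_factor")
  }
  segment * alpha
}

#' Temporal-scale perturbation with synchronized labels
#'
#' Resamples the whole trial so that content originally at time `t` appears
#' at `beta * t` (linear interpolation), keeping the original sample count:
#' for `beta > 1` the stretched tail is cropped, for `beta < 1` the freed
#' tail is zero-padded. Onset and offset are multiplied by the exact same
#' factor (offset clipped to the trial duration). The perturbation operates
#' on whole trials before windowing because the label-scaling rule is only
#' coherent on the trial time base.
#'
#' @param trial a `semg_trial`.
#' @param beta positive temporal factor.
#' @return the augmented `semg_trial`.
#' @export
temporal_scale <- function(trial, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    abort("temporal factor must be a single positive number", "slowonset_bad_factor")
  }
  if (beta == 1) return(trial)
  dur <- trial_duration_ms(trial)
  if (!is.na(trial$onset_ms) && trial$onset_ms * beta >= dur) {
    abort(sprintf("scaled onset %.1f ms falls outside the %.0f ms trial",
                  trial$onset_ms * beta, dur), "slowonset_rejected_augmentation")
  }
  n <- ncol(trial$signal)
  src <- (seq_len(n) - 1) / beta + 1       # sample i' reads original time (i'-1)/beta
  inside <- src <= n
  out <- matrix(0, nrow = nrow(trial$signal), ncol = n)
  for (ch in seq_len(nrow(trial$signal))) {
    out[ch, inside] <- approx(seq_len(n), trial$signal[ch, ], xout = src[inside])$y
  }
  trial$signal <- out
  if (!is.na(trial$onset_ms)) {
    trial$onset_ms <- trial$onset_ms * beta
    trial$offset_ms <- min(trial$offset_ms * beta, dur)
  }
  trial
}
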