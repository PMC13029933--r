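`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(message, class) {
  stop(structure(
    class = c(class, "slowonset_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Derive a reproducible substream seed
#'
#' One global seed drives every source of randomness in the package; nested
#' generators (per subject, per trial, per epoch) draw their own seed from it
#' through this counter scheme, so datasets can be regenerated piecewise
#' without replaying the whole stream. The scheme is a Lehmer-style integer
#' mix, kept strictly below 2^31.
#'
#' @param seed integer base seed.
#' @param ... further non-negative integer counters (e.g. subject index,
#'   trial index), mixed in order.
#' @return an integer in `[0, 2147483562]` usable with [set.seed()].
#' @export
#' @examples
#' substream_seed(42, 3, 7)
substream_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483563
  for (i in idx) {
    s <- (s * 48271 + as.double(i) + 1) %% 2147483563
  }
  as.integer(s)
}

## ms -> whole samples, failing loudly on non-integer conversions
ms_to_samples <- function(ms, fs, what = "duration") {
  x <- ms * fs / 1000
  r <- round(x)
  if (any(abs(x - r) > 1e-6)) {
    abort(sprintf("%s of %s ms is not a whole number of samples at fs = %s Hz",
                  what, paste(ms, collapse = ", "), fs),
          "slowonset_bad_grid")
  }
  as.integer(r)
}

sample_to_ms <- function(i, fs) (i - 1) / fs * 1000

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && abs(x - round(x)) < 1e-8

check_signal_matrix <- function(signal) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric channels x samples matrix", "slowonset_bad_input")
  }
  if (any(!is.finite(signal))) {
    abort("`signal` contains non-finite values", "slowonset_bad_input")
  }
  invisible(signal)
}
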