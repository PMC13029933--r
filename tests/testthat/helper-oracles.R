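# Independent brute-force oracles used across tests. Everything here is
# written with explicit scalar loops so it shares no code path with the
# package's vectorized/compiled implementations.

# plain scalar-loop 1D convolution: out[k, t] = b[k] + sum_c sum_j
# W[k, c, j] * x[c, t + offs[j]] with zeros outside 1..T
slow_conv <- function(x, W, b, offs) {
  C <- nrow(x); T <- ncol(x); K <- dim(W)[3]; Cout <- dim(W)[1]
  out <- matrix(0, Cout, T)
  for (k in seq_len(Cout)) for (t in seq_len(T)) {
    acc <- b[k]
    for (j in seq_len(K)) {
      s <- t + offs[j]
      if (s >= 1 && s <= T) {
        for (c in seq_len(C)) acc <- acc + W[k, c, j] * x[c, s]
      }
    }
    out[k, t] <- acc
  }
  out
}

# local-context sequence: Z[, s] = concat(F[, s-k:s+k], F[, s]) with F
# zero-padded; built for an extended index range so the following width-3
# convolution can be applied literally at every t in 1..T
slow_context <- function(F, k, margin = 1) {
  C <- nrow(F); T <- ncol(F)
  fcol <- function(s) if (s >= 1 && s <= T) F[, s] else rep(0, C)
  sapply((1 - margin):(T + margin), function(s) {
    c(unlist(lapply((s - k):(s + k), fcol)), fcol(s))
  })
}

# per-timestep attention oracle: two width-3 convs (ReLU between), 1x1
# projection, sigmoid - computed with scalar loops on the extended context
slow_attention <- function(F, net) {
  cfg <- net$cfg; p <- net$params
  k <- cfg$radius; T <- ncol(F)
  Zext <- slow_context(F, k, margin = 2)      # covers indices -1 .. T+2
  at <- function(s) s + 2                      # column of index s in Zext
  A1 <- function(t) {                          # width-3 conv over Z at index t
    sapply(seq_len(cfg$att_hidden), function(kk) {
      acc <- p$att1$b[kk]
      for (j in 1:3) {
        s <- t + c(-1L, 0L, 1L)[j]
        acc <- acc + sum(p$att1$W[kk, , j] * Zext[, at(s)])
      }
      acc
    })
  }
  alpha <- numeric(T)
  for (t in seq_len(T)) {
    ## the second convolution zero-pads the hidden sequence at its edges
    r1 <- lapply((t - 1):(t + 1), function(s) {
      if (s < 1 || s > T) rep(0, cfg$att_hidden) else pmax(A1(s), 0)
    })
    a2 <- sapply(seq_len(cfg$att_compressed), function(kk) {
      acc <- p$att2$b[kk]
      for (j in 1:3) acc <- acc + sum(p$att2$W[kk, , j] * r1[[j]])
      acc
    })
    z <- sum(p$att3$W[1, , 1] * a2) + p$att3$b[1]
    alpha[t] <- 1 / (1 + exp(-z))
  }
  alpha
}

# one gated stable unit recomputed branch by branch
slow_stable_unit <- function(x, Wu, bu, Wv, bv) {
  U <- slow_conv(x, Wu, bu, -1:1)
  V <- slow_conv(x, Wv, bv, -1:1)
  tanh(U) * (1 / (1 + exp(-V)))
}

# exhaustive trailing-mean decision scan
slow_decision <- function(y, theta, W) {
  n <- length(y)
  out <- rep(FALSE, n)
  for (t in seq_len(n)) {
    if (t < W) next
    out[t] <- mean(y[(t - W + 1):t]) > theta
  }
  out
}

# analytic magnitude of the digital Butterworth band-pass of total order 2n
# (bilinear transform with prewarped edge frequencies)
butter_bp_gain <- function(f, low, high, fs, n = 2) {
  nu <- function(x) tan(pi * x / fs)
  v <- nu(f)
  1 / sqrt(1 + ((v^2 - nu(low) * nu(high)) / (v * (nu(high) - nu(low))))^(2 * n))
}

# small deterministic single-channel ramp trial: signal IS the envelope
ramp_trial <- function(onset_ms = 400, rise_ms = 600, fs = 1000,
                       duration_ms = 2000) {
  t_ms <- (0:(duration_ms * fs / 1000 - 1)) / fs * 1000
  env <- activation_envelope(t_ms, onset_ms, rise_ms)
  new_trial(subject_id = "S01", fs = fs, signal = matrix(env, nrow = 1),
            onset_ms = onset_ms, offset_ms = duration_ms,
            provenance = "synthetic")
}

tiny_net_cfg <- function(seed = 1) {
  net_config(in_channels = 2, enc_channels = 4, enc_kernel = 3,
             enc_layers = 2, radius = 2, att_hidden = 5, att_compressed = 4,
             unit1_width = 3, stable_width = 4, n_units = 3, head_width = 3,
             init_seed = seed)
}

# small simulation config that keeps unit tests fast; any field can be
# overridden by name
small_sim_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 2, trials_per_subject = 3, duration_ms = 2000,
         ramp_start_range_ms = c(300, 600),
         ramp_duration_range_ms = c(300, 800)),
    list(...))
  do.call(sim_config, args)
}
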