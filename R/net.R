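#' Detection network configuration
#'
#' Architecture of the lightweight temporal-attention detector. The paper-
#' fixed hyperparameters are the attention widths (`att_hidden` = 32,
#' `att_compressed` = 16), the neighbourhood radius (`radius` = 2) and the
#' three stable decision units of width `stable_width` = 16. The free widths
#' (`enc_channels`, `unit1_width`, `head_width`, `enc_kernel`, `enc_layers`)
#' were calibrated once with [calibrate_net_widths()] so that the total
#' trainable-parameter count equals 24580, and are frozen here as defaults.
#'
#' @param in_channels number of sEMG input channels.
#' @param enc_channels encoder output channels C'.
#' @param enc_kernel encoder kernel width K (odd).
#' @param enc_layers 1 or 2 encoder layers; the second is a 1x1 channel map.
#' @param radius neighbourhood radius k of the attention context.
#' @param att_hidden attention hidden width Ca.
#' @param att_compressed attention compressed width Cb.
#' @param unit1_width width of the first stable decision unit.
#' @param stable_width width Cs of the remaining stable decision units.
#' @param n_units number of stable decision units.
#' @param head_width hidden width of the confidence head.
#' @param init_seed seed for weight initialization.
#' @return an object of class `net_config`.
#' @export
net_config <- function(in_channels = 6, enc_channels = 28, enc_kernel = 5,
                       enc_layers = 2, radius = 2, att_hidden = 32,
                       att_compressed = 16, unit1_width = 12,
                       stable_width = 16, n_units = 3, head_width = 21,
                       init_seed = 42) {
  stopifnot(radius >= 1, enc_kernel %% 2 == 1, enc_layers %in% 1:2,
            n_units >= 1)
  widths <- c(in_channels, enc_channels, att_hidden, att_compressed,
              unit1_width, stable_width, head_width)
  if (any(widths < 1)) abort("all widths must be >= 1", "slowonset_bad_config")
  structure(list(
    in_channels = in_channels, enc_channels = enc_channels,
    enc_kernel = enc_kernel, enc_layers = enc_layers, radius = radius,
    att_hidden = att_hidden, att_compressed = att_compressed,
    unit1_width = unit1_width, stable_width = stable_width,
    n_units = n_units, head_width = head_width, init_seed = init_seed
  ), class = "net_config")
}

## Layer table: name, in channels, out channels, kernel offsets.
## Encoder offsets are causal (output at t reads t-K+1..t); all 3-wide
## convolutions are centred; 1x1 maps have a single zero offset.
net_layer_shapes <- function(cfg) {
  k <- cfg$radius
  zch <- cfg$enc_channels * (2 * k + 2)
  shapes <- list(
    enc1 = list(cin = cfg$in_channels, cout = cfg$enc_channels,
                offs = -(0:(cfg$enc_kernel - 1)))
  )
  if (cfg$enc_layers == 2) {
    shapes$enc2 <- list(cin = cfg$enc_channels, cout = cfg$enc_channels, offs = 0L)
  }
  shapes$att1 <- list(cin = zch, cout = cfg$att_hidden, offs = -1:1)
  shapes$att2 <- list(cin = cfg$att_hidden, cout = cfg$att_compressed, offs = -1:1)
  shapes$att3 <- list(cin = cfg$att_compressed, cout = 1L, offs = 0L)
  unit_widths <- c(cfg$unit1_width, rep(cfg$stable_width, cfg$n_units - 1))
  cin <- cfg$enc_channels
  for (u in seq_len(cfg$n_units)) {
    shapes[[sprintf("u%du", u)]] <- list(cin = cin, cout = unit_widths[u], offs = -1:1)
    shapes[[sprintf("u%dv", u)]] <- list(cin = cin, cout = unit_widths[u], offs = -1:1)
    cin <- unit_widths[u]
  }
  shapes$head1 <- list(cin = cin, cout = cfg$head_width, offs = 0L)
  shapes$head2 <- list(cin = cfg$head_width, cout = 1L, offs = 0L)
  shapes
}

#' Count the trainable parameters of the detection network
#'
#' Sums the element counts of every weight and bias tensor. Works on either
#' a `net_config` (analytic, from the layer shapes) or an instantiated
#' `onset_net` (by measuring the actual tensors).
#'
#' @param x a [net_config()] or [init_net()] result.
#' @return integer parameter count.
#' @export
#' @examples
#' count_parameters(net_config())
count_parameters <- function(x) UseMethod("count_parameters")

#' @export
count_parameters.net_config <- function(x) {
  shapes <- net_layer_shapes(x)
  sum(vapply(shapes, function(s) s$cout * s$cin * length(s$offs) + s$cout, numeric(1)))
}

#' @export
count_parameters.onset_net <- function(x) {
  sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' Instantiate the detection network
#'
#' Weights are drawn from a fan-in-scaled uniform distribution
#' `U(-sqrt(3/fan_in), sqrt(3/fan_in))` (unit-variance preserving for
#' zero-mean inputs, so the confidence head sees usable signal from the
#' first epoch) under the configured seed; biases start at zero.
#'
#' @param cfg a [net_config()].
#' @return an object of class `onset_net` holding the parameter list and the
#'   config.
#' @export
init_net <- function(cfg = net_config()) {
  shapes <- net_layer_shapes(cfg)
  set.seed(cfg$init_seed)
  params <- lapply(shapes, function(s) {
    a <- sqrt(3 / (s$cin * length(s$offs)))
    list(W = array(runif(s$cout * s$cin * length(s$offs), -a, a),
                   dim = c(s$cout, s$cin, length(s$offs))),
         b = rep(0, s$cout),
         offs = as.integer(s$offs))
  })
  structure(list(params = params, cfg = cfg), class = "onset_net")
}

#' @export
print.onset_net <- function(x, ...) {
  cat(sprintf("<onset_net> %d layers, %d trainable parameters\n",
              length(x$params), count_parameters(x)))
  invisible(x)
}

## ---- batched primitives --------------------------------------------------
## Batches are arrays [channels, T, B]; zero padding is implicit at sequence
## edges. Convolutions are realized as one matrix product per kernel offset.

as_batch <- function(x) {
  if (is.matrix(x)) array(x, dim = c(nrow(x), ncol(x), 1)) else x
}

kernel_slice <- function(W, j) {
  Wj <- W[, , j, drop = FALSE]
  dim(Wj) <- dim(W)[1:2]
  Wj
}

conv_fwd <- function(X, layer) {
  conv1d_fwd_cpp(X, layer$W, layer$b, as.integer(layer$offs))
}

conv_bwd <- function(dY, X, layer) {
  conv1d_bwd_cpp(dY, X, layer$W, as.integer(layer$offs))
}

## local context: stack F at offsets -k..k plus the reference frame
context_fwd <- function(F, k) {
  d <- dim(F); C <- d[1]; T <- d[2]; B <- d[3]
  offs <- c(-k:k, 0L)
  Z <- array(0, dim = c(C * length(offs), T, B))
  for (j in seq_along(offs)) {
    o <- offs[j]
    ts <- max(1, 1 - o):min(T, T - o)
    rows <- (j - 1) * C + seq_len(C)
    Z[rows, ts, ] <- F[, ts + o, , drop = FALSE]
  }
  Z
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## The first attention convolution acts on the local-context sequence
## Z_s = Concat(F[, s-k : s+k], F[, s]) (out-of-range F columns are zero).
## Stacking shifted copies of F and convolving with a width-3 kernel is
## algebraically one convolution on F whose taps cover offsets
## -(k+1) .. (k+1): W_eff[, , o] = sum over kernel tap j and context block b
## with off(j) + off(b) = o of W1[, rows_b, j]. The fused form avoids ever
## materializing the (2k+2)C'-channel context tensor.
fuse_attention_layer <- function(layer, k, C) {
  offs_b <- c(-k:k, 0L)
  offs_j <- layer$offs
  offs <- (min(offs_j) + min(offs_b)):(max(offs_j) + max(offs_b))
  W_eff <- array(0, dim = c(dim(layer$W)[1], C, length(offs)))
  for (j in seq_along(offs_j)) for (b in seq_along(offs_b)) {
    o <- offs_j[j] + offs_b[b]
    rows <- (b - 1) * C + seq_len(C)
    W_eff[, , o - min(offs) + 1L] <- W_eff[, , o - min(offs) + 1L] +
      layer$W[, rows, j]
  }
  list(W = W_eff, b = layer$b, offs = as.integer(offs))
}

## scatter the fused weight gradient back onto the unfused kernel: each
## (tap, block) pair receives the full gradient of its combined offset
unfuse_attention_grad <- function(dW_eff, layer, k, C) {
  offs_b <- c(-k:k, 0L)
  offs_j <- layer$offs
  o_min <- min(offs_j) + min(offs_b)
  dW <- array(0, dim = dim(layer$W))
  for (j in seq_along(offs_j)) for (b in seq_along(offs_b)) {
    o <- offs_j[j] + offs_b[b]
    rows <- (b - 1) * C + seq_len(C)
    dW[, rows, j] <- dW_eff[, , o - o_min + 1L]
  }
  dW
}

## full forward pass with cached intermediates (training path)
net_forward_cache <- function(X, net) {
  p <- net$params
  cfg <- net$cfg
  cache <- list(X = X)
  H <- conv_fwd(X, p$enc1)
  if (!is.null(p$enc2)) {
    cache$F_pre <- H
    H <- conv_fwd(H, p$enc2)
  }
  cache$F <- H
  att1f <- fuse_attention_layer(p$att1, cfg$radius, cfg$enc_channels)
  cache$att1f <- att1f
  A1 <- conv_fwd(H, att1f); R1 <- pmax(A1, 0)
  A2 <- conv_fwd(R1, p$att2)
  A3 <- conv_fwd(A2, p$att3)
  alpha <- sigmoid(A3)
  cache$A1 <- A1; cache$R1 <- R1; cache$A2 <- A2; cache$alpha <- alpha
  Ft <- sweep_alpha(H, alpha)
  cache$Ft <- Ft
  S <- Ft
  for (u in seq_len(cfg$n_units)) {
    U <- conv_fwd(S, p[[sprintf("u%du", u)]])
    V <- conv_fwd(S, p[[sprintf("u%dv", u)]])
    tU <- tanh(U); sV <- sigmoid(V)
    cache[[sprintf("Sin%d", u)]] <- S
    cache[[sprintf("tU%d", u)]] <- tU
    cache[[sprintf("sV%d", u)]] <- sV
    S <- tU * sV
  }
  cache$S <- S
  H1 <- conv_fwd(S, p$head1); RH <- pmax(H1, 0)
  ZL <- conv_fwd(RH, p$head2)           # logits, [1, T, B]
  cache$H1 <- H1; cache$RH <- RH; cache$logits <- ZL
  cache$y <- sigmoid(ZL)
  cache
}

## multiply every channel of F by the scalar trace alpha [1, T, B]
sweep_alpha <- function(F, alpha) {
  d <- dim(F)
  F * array(rep(alpha, each = d[1]), dim = d)
}

## backward pass from d(logits); returns gradient list parallel to params
net_backward <- function(cache, dlogits, net) {
  p <- net$params
  cfg <- net$cfg
  g <- list()
  bw <- conv_bwd(dlogits, cache$RH, p$head2)
  g$head2 <- bw[c("dW", "db")]
  dRH <- bw$dX * (cache$H1 > 0)
  bw <- conv_bwd(dRH, cache$S, p$head1)
  g$head1 <- bw[c("dW", "db")]
  dS <- bw$dX
  for (u in rev(seq_len(cfg$n_units))) {
    tU <- cache[[sprintf("tU%d", u)]]
    sV <- cache[[sprintf("sV%d", u)]]
    Sin <- cache[[sprintf("Sin%d", u)]]
    dU <- dS * sV * (1 - tU^2)
    dV <- dS * tU * sV * (1 - sV)
    bwU <- conv_bwd(dU, Sin, p[[sprintf("u%du", u)]])
    bwV <- conv_bwd(dV, Sin, p[[sprintf("u%dv", u)]])
    g[[sprintf("u%du", u)]] <- bwU[c("dW", "db")]
    g[[sprintf("u%dv", u)]] <- bwV[c("dW", "db")]
    dS <- bwU$dX + bwV$dX
  }
  ## dS is now the gradient at Ft = alpha * F
  alpha <- cache$alpha
  F <- cache$F
  dF <- sweep_alpha(dS, alpha)                      # alpha broadcast over channels
  dalpha <- array(colSums(dS * F, dims = 1), dim = dim(alpha))
  dA3 <- dalpha * alpha * (1 - alpha)
  bw <- conv_bwd(dA3, cache$A2, p$att3)
  g$att3 <- bw[c("dW", "db")]
  bw <- conv_bwd(bw$dX, cache$R1, p$att2)
  g$att2 <- bw[c("dW", "db")]
  dR1 <- bw$dX * (cache$A1 > 0)
  bw <- conv_bwd(dR1, cache$F, cache$att1f)
  g$att1 <- list(dW = unfuse_attention_grad(bw$dW, p$att1, cfg$radius,
                                            cfg$enc_channels),
                 db = bw$db)
  dF <- dF + bw$dX
  if (!is.null(p$enc2)) {
    bw <- conv_bwd(dF, cache$F_pre, p$enc2)
    g$enc2 <- bw[c("dW", "db")]
    dF <- bw$dX
  }
  bw <- conv_bwd(dF, cache$X, p$enc1)
  g$enc1 <- bw[c("dW", "db")]
  g[names(net$params)]
}

## ---- exported stage operations (single window) ----------------------------

#' Encode a window with the shallow temporal encoder
#'
#' One causal 1D convolution (output at `t` reads offsets `t-K+1 .. t`) with
#' same-length zero padding, optionally followed by a 1x1 channel map.
#' Temporal length is preserved.
#'
#' @param X channels x T window matrix.
#' @param net an [init_net()] result.
#' @return a C' x T feature matrix.
#' @export
encode <- function(X, net) {
  if (nrow(X) != net$cfg$in_channels) {
    abort(sprintf("window has %d channels; network expects %d",
                  nrow(X), net$cfg$in_channels), "slowonset_shape_error")
  }
  H <- conv_fwd(as_batch(X), net$params$enc1)
  if (!is.null(net$params$enc2)) H <- conv_fwd(H, net$params$enc2)
  H[, , 1]
}

#' Local temporal context block
#'
#' Channel-wise concatenation of the neighbourhood frames
#' `F[, (t-k):(t+k)]` (zero-padded at the sequence edges) with the reference
#' frame `F[, t]`, giving `C' * (2k + 2)` channels.
#'
#' @param F C' x T feature matrix.
#' @param t 1-based time index.
#' @param k neighbourhood radius.
#' @return numeric vector of length `C' * (2k + 2)`.
#' @export
local_context <- function(F, t, k) {
  if (t < 1 || t > ncol(F)) abort("t out of range", "slowonset_bad_input")
  Z <- context_fwd(as_batch(F), k)
  Z[, t, 1]
}

#' Per-time-step attention trace
#'
#' The context blocks are transformed by two shared 3-wide stride-1
#' convolutions (to Ca channels, ReLU, then to Cb channels) and a 1x1
#' projection, and squashed through a sigmoid, producing one attention
#' weight in `[0, 1]` per time step. Parameters are shared across t, so the
#' whole trace is computed as convolutions over the sequence; context blocks
#' outside the window are built from the zero-padded feature map.
#'
#' @param F C' x T feature matrix (from [encode()]).
#' @param net an [init_net()] result.
#' @return numeric vector alpha of length T, values in `[0, 1]`.
#' @export
attention_trace <- function(F, net) {
  p <- net$params
  att1f <- fuse_attention_layer(p$att1, net$cfg$radius, net$cfg$enc_channels)
  A1 <- pmax(conv_fwd(as_batch(F), att1f), 0)
  A2 <- conv_fwd(A1, p$att2)
  as.numeric(sigmoid(conv_fwd(A2, p$att3)))
}

#' Apply an attention trace to a feature map
#'
#' @param F C' x T feature matrix.
#' @param alpha attention weights of length T.
#' @return the reweighted feature matrix `F[, t] * alpha[t]`.
#' @export
apply_attention <- function(F, alpha) {
  if (length(alpha) != ncol(F)) {
    abort("attention trace length does not match the feature map",
          "slowonset_shape_error")
  }
  F * rep(alpha, each = nrow(F))
}

#' Gated stable decision stack
#'
#' Stable decision units in series; each computes two parallel 3-wide
#' stride-1 convolutions of its input and combines them as
#' `tanh(U) * sigmoid(V)` - a smoothing activation gated by a bounded gate,
#' which acts as an adaptive low-pass on the temporal sequence. Temporal
#' length is preserved throughout.
#'
#' @param Ft attention-weighted C' x T feature matrix.
#' @param net an [init_net()] result.
#' @return a Cs x T feature matrix.
#' @export
stable_stack <- function(Ft, net) {
  p <- net$params
  S <- as_batch(Ft)
  for (u in seq_len(net$cfg$n_units)) {
    U <- conv_fwd(S, p[[sprintf("u%du", u)]])
    V <- conv_fwd(S, p[[sprintf("u%dv", u)]])
    S <- tanh(U) * sigmoid(V)
  }
  S[, , 1]
}

#' Confidence head
#'
#' 1x1 projection to the head width, ReLU, 1x1 projection to one channel and
#' a sigmoid, yielding the per-time-step slow-activation confidence.
#'
#' @param S Cs x T feature matrix from [stable_stack()].
#' @param net an [init_net()] result.
#' @return numeric vector y of length T, values in `[0, 1]`.
#' @export
confidence_head <- function(S, net) {
  p <- net$params
  H <- pmax(conv_fwd(as_batch(S), p$head1), 0)
  as.numeric(sigmoid(conv_fwd(H, p$head2)))
}

#' Full forward pass on one window
#'
#' [encode()], [attention_trace()], [apply_attention()], [stable_stack()]
#' and [confidence_head()] composed; deterministic given the weights.
#'
#' @param X channels x T window matrix.
#' @param net an [init_net()] result.
#' @return numeric confidence vector of length T in `[0, 1]`.
#' @export
net_forward <- function(X, net) {
  cache <- net_forward_cache(as_batch(X), net)
  as.numeric(cache$y)
}

## batched inference: X3 [C, T, B] -> y matrix T x B
net_forward_batch <- function(X3, net) {
  cache <- net_forward_cache(X3, net)
  matrix(cache$y, nrow = dim(X3)[2])
}

#' Calibrate the free architecture widths against a parameter budget
#'
#' The attention widths, neighbourhood radius and stable-unit width are
#' architectural constants; the encoder width C', the first stable unit's
#' width and the head width are free. This search enumerates small integer
#' widths (and the encoder depth/kernel options) and returns the
#' configuration whose total parameter count equals `target` exactly,
#' preferring solutions close to the canonical widths (C' near 32, unit and
#' head widths near 16, two encoder layers, kernel 5). The result is frozen
#' as the [net_config()] defaults.
#'
#' @param target total trainable-parameter budget.
#' @param in_channels input channel count.
#' @param enc_range,unit1_range,head_range integer search ranges.
#' @return the solved `net_config`, or an error if no width combination
#'   meets the budget.
#' @export
calibrate_net_widths <- function(target = 24580L, in_channels = 6,
                                 enc_range = 4:48, unit1_range = 2:64,
                                 head_range = 2:128) {
  best <- NULL
  best_score <- Inf
  for (el in 1:2) for (K in c(3L, 5L, 7L)) for (cp in enc_range) for (h in unit1_range) {
    cfg <- net_config(in_channels = in_channels, enc_channels = cp,
                      enc_kernel = K, enc_layers = el, unit1_width = h,
                      head_width = 1)
    base <- count_parameters(cfg)           # head_width = 1 -> head has 16*1+1 + 1+1
    ## head params as a function of d: (Cs*d + d) + (d + 1) = 18 d + 1 at Cs = 16
    cs <- cfg$stable_width
    head_of <- function(d) cs * d + d + d + 1
    rem <- target - (base - head_of(1))
    d <- (rem - 1) / (cs + 2)
    if (d == round(d) && d >= min(head_range) && d <= max(head_range)) {
      score <- (cp - 32)^2 + (h - 16)^2 + (d - 16)^2 +
        1000 * (el != 2) + 250 * (K - 5)^2
      if (score < best_score) {
        best_score <- score
        best <- net_config(in_channels = in_channels, enc_channels = cp,
                           enc_kernel = K, enc_layers = el, unit1_width = h,
                           head_width = as.integer(d))
      }
    }
  }
  if (is.null(best)) {
    abort(sprintf("no width combination meets the %d-parameter budget", target),
          "slowonset_calibration_failed")
  }
  stopifnot(count_parameters(best) == target)
  best
}
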