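test_that("encoder is linear, causal and translation equivariant", {
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  ## zero input with zero biases -> zero features
  expect_true(all(encode(matrix(0, 2, 30), net) == 0))
  ## causality: perturbing the future never changes the present
  set.seed(6)
  X <- matrix(rnorm(2 * 40), 2)
  F1 <- encode(X, net)
  X2 <- X; X2[, 30:40] <- X2[, 30:40] + 5
  F2 <- encode(X2, net)
  expect_equal(F1[, 1:29], F2[, 1:29], tolerance = 1e-12)
  ## translation equivariance away from the padded edges
  s <- 7
  Xs <- cbind(matrix(0, 2, s), X)[, 1:ncol(X)]
  Fs <- encode(Xs, net)
  expect_lt(max(abs(Fs[, (s + 3):ncol(X)] - F1[, 3:(ncol(X) - s)])), 1e-6)
  expect_error(encode(matrix(0, 3, 30), net), class = "slowonset_shape_error")
})

test_that("encoder matches the scalar-loop convolution oracle", {
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  set.seed(7)
  X <- matrix(rnorm(2 * 25), 2)
  o1 <- slow_conv(X, net$params$enc1$W, net$params$enc1$b, net$params$enc1$offs)
  o2 <- slow_conv(o1, net$params$enc2$W, net$params$enc2$b, 0L)
  expect_equal(encode(X, net), o2, tolerance = 1e-12)
})

test_that("local context stacks 2k+2 frames with zero edge padding", {
  set.seed(8)
  F <- matrix(rnorm(4 * 12), 4)
  z <- local_context(F, t = 6, k = 2)
  expect_length(z, 4 * 6)
  expect_equal(z, c(F[, 4], F[, 5], F[, 6], F[, 7], F[, 8], F[, 6]))
  z1 <- local_context(F, t = 1, k = 2)
  expect_true(all(z1[1:8] == 0))
  expect_equal(z1[9:12], F[, 1])
})

test_that("attention weights live in [0,1] and match the per-timestep oracle", {
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  set.seed(9)
  F <- matrix(rnorm(4 * 30), 4)
  al <- attention_trace(F, net)
  expect_true(all(al >= 0 & al <= 1))
  expect_lt(max(abs(al - slow_attention(F, net))), 1e-5)
  ## zeroed projection gives sigmoid(0) = 0.5 everywhere
  net0 <- net
  net0$params$att3$W[] <- 0; net0$params$att3$b[] <- 0
  expect_equal(attention_trace(F, net0), rep(0.5, 30))
})

test_that("attention application is the exact elementwise product", {
  set.seed(10)
  F <- matrix(rnorm(4 * 20), 4)
  al <- runif(20)
  expect_identical(apply_attention(F, rep(1, 20)), F)
  expect_true(all(apply_attention(F, rep(0, 20)) == 0))
  oracle <- F
  for (t in 1:20) oracle[, t] <- al[t] * F[, t]
  expect_equal(apply_attention(F, al), oracle, tolerance = 1e-15)
  expect_error(apply_attention(F, al[1:10]), class = "slowonset_shape_error")
})

test_that("stable units gate as tanh(U) * sigmoid(V) and stay bounded", {
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  set.seed(11)
  x <- matrix(rnorm(4 * 25), 4)
  ## zero input, zero biases -> tanh(0) kills the output
  expect_true(all(abs(stable_stack(matrix(0, 4, 25), net)) < 1e-12))
  S <- stable_stack(x, net)
  expect_true(all(S > -1 & S < 1))
  ## single-unit oracle
  p <- net$params
  s1 <- slow_stable_unit(x, p$u1u$W, p$u1u$b, p$u1v$W, p$u1v$b)
  s2 <- slow_stable_unit(s1, p$u2u$W, p$u2u$b, p$u2v$W, p$u2v$b)
  s3 <- slow_stable_unit(s2, p$u3u$W, p$u3u$b, p$u3v$W, p$u3v$b)
  expect_lt(max(abs(S - s3)), 1e-6)
})

test_that("confidence head is bounded and matches manual recomputation", {
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  set.seed(12)
  S <- matrix(rnorm(4 * 25), 4)
  y <- confidence_head(S, net)
  expect_true(all(y >= 0 & y <= 1))
  p <- net$params
  h1 <- pmax(slow_conv(S, p$head1$W, p$head1$b, 0L), 0)
  z <- slow_conv(h1, p$head2$W, p$head2$b, 0L)
  expect_lt(max(abs(y - 1 / (1 + exp(-z)))), 1e-6)
  net0 <- net
  net0$params$head2$W[] <- 0; net0$params$head2$b[] <- 0
  expect_equal(confidence_head(S, net0), rep(0.5, 25))
})

test_that("full forward preserves length, is deterministic and composes the stages", {
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  for (T in c(50, 250, 1000)) {
    set.seed(T)
    X <- matrix(rnorm(2 * T), 2)
    y <- net_forward(X, net)
    expect_length(y, T)
    expect_identical(y, net_forward(X, net))
    staged <- confidence_head(
      stable_stack(apply_attention(encode(X, net), attention_trace(encode(X, net), net)), net),
      net)
    expect_lt(max(abs(y - staged)), 1e-5)
  }
})

test_that("parameter counting matches closed forms and the module-wise tally", {
  ## one convolution, 2 -> 3 channels, width 3, with bias
  one <- net_config(in_channels = 2, enc_channels = 3, enc_kernel = 3,
                    enc_layers = 1, unit1_width = 2, head_width = 2)
  shapes <- slowonset:::net_layer_shapes(one)
  expect_equal(shapes$enc1$cout * shapes$enc1$cin * length(shapes$enc1$offs) +
                 shapes$enc1$cout, 21)
  ## whole-model count equals the per-layer tally on an instantiated net
  cfg <- tiny_net_cfg()
  net <- init_net(cfg)
  tally <- sum(vapply(net$params, function(p) length(p$W) + length(p$b), numeric(1)))
  expect_equal(count_parameters(cfg), tally)
  expect_equal(count_parameters(net), tally)
})

test_that("floating-point cost grows linearly with the window length", {
  cfg <- net_config()
  shapes <- slowonset:::net_layer_shapes(cfg)
  macs_per_t <- sum(vapply(shapes, function(s) s$cout * s$cin * length(s$offs),
                           numeric(1)))
  cost <- function(T) macs_per_t * T   # every stage is a stride-1 convolution
  expect_lt(abs(cost(500) / cost(250) - 2), 0.05 * 2)
})

test_that("width calibration reproduces the frozen default configuration", {
  solved <- calibrate_net_widths(24580L)
  expect_equal(count_parameters(solved), 24580)
  def <- net_config()
  expect_equal(solved$enc_channels, def$enc_channels)
  expect_equal(solved$unit1_width, def$unit1_width)
  expect_equal(solved$head_width, def$head_width)
  expect_equal(solved$enc_kernel, def$enc_kernel)
  expect_equal(solved$enc_layers, def$enc_layers)
})
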