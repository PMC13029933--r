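test_that("stitching averages overlapping windows and matches a cover-counting oracle", {
  fs <- 1000
  ## single cover is the identity
  y <- runif(250)
  st <- stitch(list(y), 0, fs)
  expect_equal(st$y, y)
  ## two half-overlapping constant windows
  st2 <- stitch(list(rep(0.2, 100), rep(0.6, 100)), c(0, 50), fs)
  expect_equal(st2$y[1:50], rep(0.2, 50))
  expect_equal(st2$y[51:100], rep(0.4, 50))
  expect_equal(st2$y[101:150], rep(0.6, 50))
  ## random overlap pattern vs per-sample accumulation
  set.seed(13)
  starts <- c(0, 30, 60, 90, 120)
  traces <- lapply(starts, function(s) runif(100))
  st3 <- stitch(traces, starts, fs)
  n <- 220
  acc <- numeric(n); cov <- numeric(n)
  for (i in seq_along(starts)) {
    idx <- (starts[i] + 1):(starts[i] + 100)
    acc[idx] <- acc[idx] + traces[[i]]; cov[idx] <- cov[idx] + 1
  }
  expect_equal(st3$y, acc / cov, tolerance = 1e-9)
  ## a coverage gap is an error
  expect_error(stitch(list(runif(50), runif(50)), c(0, 100), fs),
               class = "slowonset_coverage_error")
})

test_that("continuity decision uses a strict trailing-mean criterion", {
  fs <- 1000
  cfg <- decision_config(theta = 0.75, omega_ms = 5)
  tr <- confidence_trace(rep(0.9, 20), fs)
  dec <- continuity_decision(tr, cfg)
  expect_equal(which(dec)[1], 5)            # first complete trailing window
  ## an isolated unit spike cannot trigger
  y <- rep(0, 50); y[20] <- 1
  expect_false(any(continuity_decision(confidence_trace(y, fs), cfg)))
  ## a window mean exactly at theta stays inactive
  cfg2 <- decision_config(theta = 0.8, omega_ms = 5)
  expect_false(any(continuity_decision(confidence_trace(rep(0.8, 30), fs), cfg2)))
})

test_that("detect_onset equals the exhaustive scan oracle on random traces", {
  fs <- 1000
  for (i in 1:20) {
    set.seed(100 + i)
    y <- pmin(pmax(cumsum(rnorm(400, 0.004, 0.02)), 0), 1)
    cfg <- decision_config(theta = 0.6, omega_ms = 25)
    pred <- detect_onset(confidence_trace(y, fs), cfg)
    oracle <- slow_decision(y, 0.6, 25)
    hit <- which(oracle)[1]
    if (is.na(hit)) expect_true(is.na(pred$onset_ms))
    else expect_equal(pred$onset_ms, (hit - 1) / fs * 1000)
  }
  expect_true(is.na(detect_onset(confidence_trace(rep(0, 200), fs))$onset_ms))
})

test_that("a step trace triggers once the strict trailing mean crosses theta", {
  fs <- 1000
  y <- c(rep(0, 500), rep(1, 500))              # step at 500 ms
  cfg <- decision_config(theta = 0.75, omega_ms = 100)
  pred <- detect_onset(confidence_trace(y, fs), cfg)
  W <- 100
  expected_idx <- 501 + floor(0.75 * W)         # floor(theta * W) + 1 ones
  expect_equal(which(slow_decision(y, 0.75, W))[1], expected_idx)
  expect_equal(pred$onset_ms, (expected_idx - 1) / fs * 1000)
})

test_that("raising theta never makes a detection earlier", {
  fs <- 1000
  set.seed(14)
  for (i in 1:10) {
    y <- pmin(pmax(cumsum(rnorm(600, 0.003, 0.03)), 0), 1)
    tr <- confidence_trace(y, fs)
    prev <- -Inf
    for (th in seq(0.4, 0.9, by = 0.1)) {
      on <- detect_onset(tr, decision_config(theta = th, omega_ms = 50))$onset_ms
      if (is.na(on)) break
      expect_gte(on, prev)
      prev <- on
    }
  }
})

test_that("false triggers on noise become rarer as the decision window grows", {
  fs <- 1000
  set.seed(15)
  counts <- c()
  for (W in c(5, 25, 50)) {
    cfg <- decision_config(theta = 0.75, omega_ms = W)
    trig <- 0
    for (i in 1:200) {
      y <- stats::rbeta(800, 6.5, 3.5)    # i.i.d. confidence noise, mean 0.65
      if (any(continuity_decision(confidence_trace(y, fs), cfg))) trig <- trig + 1
    }
    counts <- c(counts, trig)
  }
  expect_true(all(diff(counts) < 0))
})

test_that("decision tuning equals an independent double-loop grid search", {
  fs <- 1000
  set.seed(16)
  traces <- list(); onsets <- c()
  for (i in 1:4) {                       # activation trials: ramp to ~0.9
    on <- 200 + 50 * i
    y <- c(rep(0.15, on), rep(0.9, 600 - on)) + rnorm(600, 0, 0.05)
    traces[[i]] <- confidence_trace(pmin(pmax(y, 0), 1), fs)
    onsets <- c(onsets, on)
  }
  for (i in 5:6) {                       # rest trials
    y <- rnorm(600, 0.2, 0.05)
    traces[[i]] <- confidence_trace(pmin(pmax(y, 0), 1), fs)
    onsets <- c(onsets, NA)
  }
  base <- decision_config(theta_grid = c(0.5, 0.6, 0.7), omega_grid_ms = c(50, 100))
  tuned <- tune_decision(traces, onsets, base, L_ms = 250, S_ms = 50)
  ## brute-force oracle over the same grid
  best <- NULL; best_ode <- Inf; best_fpr <- Inf
  for (th in c(0.5, 0.6, 0.7)) for (om in c(50, 100)) {
    cand <- decision_config(theta = th, omega_ms = om)
    errs <- c()
    for (i in 1:4) {
      p <- detect_onset(traces[[i]], cand)$onset_ms
      if (!is.na(p)) errs <- c(errs, abs(p - onsets[i]))
    }
    ode <- if (length(errs)) mean(errs) else Inf
    flags <- c()
    for (i in 5:6) {
      dec <- continuity_decision(traces[[i]], cand)
      nw <- (600 - 250) %/% 50 + 1
      flags <- c(flags, vapply(seq_len(nw), function(w) {
        any(dec[((w - 1) * 50 + 1):((w - 1) * 50 + 250)])
      }, logical(1)))
    }
    fpr <- mean(flags)
    better <- ode < best_ode - 1e-12 ||
      (abs(ode - best_ode) <= 1e-12 && fpr < best_fpr - 1e-12)
    if (better) { best_ode <- ode; best_fpr <- fpr; best <- cand }
  }
  expect_equal(tuned$theta, best$theta)
  expect_equal(tuned$omega_ms, best$omega_ms)
})

test_that("singleton grids and full ties fall back to the documented tie-breaks", {
  fs <- 1000
  tr <- list(confidence_trace(rep(0, 300), fs))
  one <- decision_config(theta_grid = 0.65, omega_grid_ms = 150)
  tuned <- tune_decision(tr, NA_real_, one)
  expect_equal(tuned$theta, 0.65)
  expect_equal(tuned$omega_ms, 150)
  ## all-zero traces tie everywhere: smallest theta then smallest omega
  grid <- decision_config(theta_grid = c(0.5, 0.7), omega_grid_ms = c(50, 100))
  tuned2 <- tune_decision(tr, NA_real_, grid)
  expect_equal(tuned2$theta, 0.5)
  expect_equal(tuned2$omega_ms, 50)
  expect_error(tune_decision(list(), numeric(0)), class = "slowonset_bad_input")
})
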