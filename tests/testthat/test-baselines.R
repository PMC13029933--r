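test_that("the envelope is a rectified channel-mean moving average", {
  fs <- 1000
  expect_true(all(semg_envelope(matrix(0, 2, 500), fs) == 0))
  sq <- matrix(rep(c(1, -1), 250), nrow = 1)
  env <- semg_envelope(sq, fs, smooth_ms = 100)
  expect_equal(env[100:400], rep(1, 301), tolerance = 1e-12)
  ## direct recomputation oracle
  set.seed(17)
  x <- matrix(rnorm(2 * 400), 2)
  env2 <- semg_envelope(x, fs, smooth_ms = 21)
  r <- colMeans(abs(x))
  oracle <- vapply(seq_along(r), function(t) {
    lo <- max(1, t - 10); hi <- min(length(r), t + 10)
    mean(r[lo:hi])
  }, numeric(1))
  expect_equal(env2, oracle, tolerance = 1e-12)
})

test_that("fixed threshold reports the first strict crossing", {
  fs <- 1000
  env <- c(rep(0, 500), rep(1, 500))
  expect_equal(fixed_threshold_onset(env, fs, 0.5), 500)
  expect_true(is.na(fixed_threshold_onset(rep(0.2, 100), fs, 0.5)))
  set.seed(18)
  e <- abs(rnorm(800))
  oracle <- which(e > 1.3)[1]
  expect_equal(fixed_threshold_onset(e, fs, 1.3), (oracle - 1) / fs * 1000)
  expect_error(fixed_threshold_onset(env, fs, 0), class = "slowonset_bad_config")
})

test_that("adaptive threshold derives mean + h*sd from the rest segment", {
  fs <- 1000
  env <- c(rep(0.1, 500), rep(0.1, 200), rep(0.5, 300))
  ## zero baseline sd: threshold is the baseline mean
  on <- adaptive_threshold_onset(env, fs, baseline_ms = 500, h = 3)
  expect_equal(on, 700)
  ## explicit arithmetic: mean .1 sd .02 h 3 -> threshold .16
  expect_equal(0.1 + 3 * 0.02, 0.16)
  set.seed(19)
  e <- c(abs(rnorm(500, 0.1, 0.02)), abs(rnorm(500, 0.1, 0.02)))
  thr <- mean(e[1:500]) + 3 * sd(e[1:500])
  oracle <- which(e[501:1000] > thr)[1]
  got <- adaptive_threshold_onset(e, fs, 500, 3)
  if (is.na(oracle)) expect_true(is.na(got))
  else expect_equal(got, (500 + oracle - 1) / fs * 1000)
  expect_error(adaptive_threshold_onset(e[1:400], fs, 500, 3),
               class = "slowonset_bad_input")
})

test_that("sliding statistic crosses where the trailing-mean closed form says", {
  fs <- 1000
  ## stat never leaves zero -> no onset
  flat <- matrix(rep(c(0.2, -0.2), 500), nrow = 1)
  expect_true(is.na(sliding_stat_onset(flat, fs, 100, 3, 500, smooth_ms = 1)))
  ## linear ramp in the envelope: z(t) = (ramp trailing mean - mu)/sigma
  set.seed(20)
  n <- 1500
  base <- 0.5
  slope <- 1e-3
  env <- c(rep(base, 600), base + slope * (1:900))
  sig <- matrix(env * rep(c(1, -1), length.out = n), nrow = 1)
  got <- sliding_stat_onset(sig, fs, stat_window_ms = 100, stat_thr = 3,
                            baseline_ms = 500, smooth_ms = 1)
  ## baseline sd of a constant segment is 0 -> crossing at the first ramp
  ## sample whose trailing mean exceeds the baseline; closed form: first t
  ## with mean of max(0, t' - 600) * slope over (t-99):t > 0 is t = 602
  expect_false(is.na(got))
  expect_lt(abs(got - 601), 3)
})

test_that("the three baselines agree on a noise-free step envelope", {
  fs <- 1000
  x <- matrix(c(rep(0, 1000), rep(1, 1000)) * rep(c(1, -1), 1000), nrow = 1)
  cfg <- baseline_config(envelope_smooth_ms = 100, fixed_thr = 0.5,
                         baseline_ms = 500, h = 3, stat_window_ms = 100,
                         stat_thr = 3)
  r1 <- detect_with_baseline(new_trial("s", fs = fs, signal = x), "fixed", cfg)
  r2 <- detect_with_baseline(new_trial("s", fs = fs, signal = x), "adaptive", cfg)
  r3 <- detect_with_baseline(new_trial("s", fs = fs, signal = x), "sliding", cfg)
  half <- 50
  for (r in list(r1, r2, r3)) expect_lt(abs(r$onset_ms - 1000), half + 60)
})

test_that("baselines are causal: truncation after the onset does not change it", {
  set.seed(21)
  cfg <- sim_config(n_subjects = 1, trials_per_subject = 1, duration_ms = 2500,
                    ramp_start_range_ms = c(800, 900),
                    ramp_duration_range_ms = c(300, 500), snr_db = 16)
  tr <- simulate_trial(cfg, "S01", seed = 44)
  tr$signal <- normalize_trial(bandpass(tr$signal, tr$fs, filter_spec()))
  bcfg <- baseline_config(fixed_thr = 0.6)
  for (m in c("fixed", "adaptive", "sliding")) {
    full <- detect_with_baseline(tr, m, bcfg)
    expect_false(is.na(full$onset_ms))
    cut <- tr
    keep <- ceiling((full$onset_ms / 1000) * tr$fs) + 120   # onset + smoothing margin
    cut$signal <- tr$signal[, 1:keep, drop = FALSE]
    cut$offset_ms <- NA; cut$onset_ms <- NA
    trunc <- detect_with_baseline(cut, m, bcfg)
    expect_equal(trunc$onset_ms, full$onset_ms)
  }
})

test_that("baseline tuning matches a brute-force search over the same grid", {
  set.seed(22)
  cfg <- small_sim_cfg(n_subjects = 1, trials_per_subject = 4, snr_db = 10)
  ds <- simulate_dataset(cfg)
  prep <- lapply(ds, function(tr) {
    tr$signal <- normalize_trial(bandpass(tr$signal, tr$fs, filter_spec()))
    tr
  })
  grid <- c(1, 3, 5)
  tuned <- tune_baseline(prep, "fixed", baseline_config(), h_grid = grid)
  envs <- lapply(prep, function(tr) semg_envelope(tr$signal, tr$fs, 100))
  pooled <- unlist(lapply(envs, function(e) e[1:500]))
  onsets <- vapply(prep, function(tr) tr$onset_ms, numeric(1))
  best_h <- NA; best_ode <- Inf
  for (h in grid) {
    thr <- mean(pooled) + h * sd(pooled)
    errs <- c()
    for (i in seq_along(prep)) {
      if (is.na(onsets[i])) next
      p <- fixed_threshold_onset(envs[[i]], 1000, thr)
      if (!is.na(p)) errs <- c(errs, abs(p - onsets[i]))
    }
    ode <- if (length(errs)) mean(errs) else Inf
    if (ode < best_ode - 1e-12) { best_ode <- ode; best_h <- h }
  }
  expect_equal(tuned$h, best_h)
})
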