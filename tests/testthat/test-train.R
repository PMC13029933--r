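test_that("subject folds partition the subjects deterministically", {
  subj <- sprintf("S%02d", 1:30)
  f <- make_subject_folds(rep(subj, each = 4), 5, seed = 42)
  expect_length(f, 30)
  expect_equal(sort(unique(f)), 1:5)
  expect_true(all(table(f) == 6))
  expect_identical(f, make_subject_folds(rep(subj, each = 4), 5, seed = 42))
  ## LOSO degenerate case
  f10 <- make_subject_folds(sprintf("S%02d", 1:10), 10, seed = 1)
  expect_true(all(table(f10) == 1))
  expect_error(make_subject_folds(subj[1:3], 5), class = "slowonset_bad_config")
})

test_that("random fold plans never leak a subject across the split", {
  for (i in 1:25) {
    set.seed(i)
    n <- sample(5:20, 1)
    k <- sample(2:min(5, n), 1)
    subj <- sprintf("P%02d", 1:n)
    f <- make_subject_folds(subj, k, seed = i)
    for (fold in 1:k) {
      expect_length(intersect(names(f)[f == fold], names(f)[f != fold]), 0)
    }
    expect_setequal(names(f), subj)
  }
})

test_that("cross-entropy loss has the right closed forms and oracle", {
  y <- c(1e-7, 1 - 1e-7); target <- c(0, 1)
  expect_lte(bce_loss(y, target), 2e-7)
  expect_equal(bce_loss(rep(0.5, 10), rep(1, 10)), log(2), tolerance = 1e-9)
  set.seed(26)
  yy <- runif(50, 0.01, 0.99); tt <- rbinom(50, 1, 0.5)
  oracle <- -mean(tt * log(yy) + (1 - tt) * log(1 - yy))
  expect_equal(bce_loss(yy, tt), oracle, tolerance = 1e-9)
  expect_error(bce_loss(yy, tt + 0.5), class = "slowonset_bad_input")
})

test_that("training contracts hold: zero epochs, determinism, leakage guard", {
  cfg <- sim_config(n_subjects = 3, trials_per_subject = 2, duration_ms = 1500,
                    ramp_start_range_ms = c(300, 500),
                    ramp_duration_range_ms = c(300, 500),
                    rest_trial_fraction = 0.5, snr_db = 16, seed = 12)
  ds <- simulate_dataset(cfg)
  subj <- dataset_subjects(ds)
  trs <- make_training_set(ds[subj %in% c("S01", "S02")])
  vas <- make_training_set(ds[subj == "S03"])
  ncfg <- tiny_net_cfg()
  ncfg$in_channels <- 6
  ## zero-epoch run returns the initial weights untouched
  fit0 <- train_model(trs, vas, ncfg, train_config(max_epochs = 0))
  expect_identical(fit0$net$params, init_net(ncfg)$params)
  expect_equal(nrow(fit0$history), 0)
  ## bit-identical reruns under the same seed
  tc <- train_config(max_epochs = 2)
  f1 <- train_model(trs, vas, ncfg, tc)
  f2 <- train_model(trs, vas, ncfg, tc)
  expect_identical(f1$net$params, f2$net$params)
  expect_equal(f1$history$val_loss, f2$history$val_loss)
  ## subject overlap is a hard failure
  expect_error(train_model(trs, trs, ncfg, tc), class = "slowonset_leakage_error")
})

test_that("a small high-SNR toy set is overfit to low training loss", {
  cfg <- sim_config(n_subjects = 2, trials_per_subject = 8, duration_ms = 1500,
                    ramp_start_range_ms = c(300, 500),
                    ramp_duration_range_ms = c(300, 500),
                    rest_trial_fraction = 0.25, snr_db = 20, seed = 77)
  ds <- simulate_dataset(cfg)
  subj <- dataset_subjects(ds)
  trs <- make_training_set(ds[subj == "S01"])   # 8 trials, 6 with activation
  vas <- make_training_set(ds[subj == "S02"])
  ## plateau patience stretched: an epoch is only two update steps here
  fit <- train_model(trs, vas, net_config(),
                     train_config(max_epochs = 80, plateau_patience = 10,
                                  early_stop_patience = 80))
  ## far below the ~0.69 base-rate entropy of these windows
  expect_lt(min(fit$history$train_loss), 0.4)
})

test_that("the learning-rate sequence only steps down by the plateau factor", {
  cfg <- sim_config(n_subjects = 2, trials_per_subject = 2, duration_ms = 1500,
                    ramp_start_range_ms = c(300, 500),
                    ramp_duration_range_ms = c(300, 500), snr_db = 16, seed = 3)
  ds <- simulate_dataset(cfg)
  subj <- dataset_subjects(ds)
  trs <- make_training_set(ds[subj == "S01"])
  vas <- make_training_set(ds[subj == "S02"])
  ncfg <- tiny_net_cfg(); ncfg$in_channels <- 6
  fit <- train_model(trs, vas, ncfg,
                     train_config(max_epochs = 25, plateau_patience = 2,
                                  early_stop_patience = 25))
  lr <- fit$history$lr
  expect_true(all(diff(lr) <= 0))
  steps <- lr[-1] / lr[-length(lr)]
  expect_true(all(abs(steps - 1) < 1e-12 | abs(steps - 0.5) < 1e-12))
  ## the restored best checkpoint is at least as good as the final epoch
  best <- min(fit$history$val_loss)
  expect_lte(best, fit$history$val_loss[nrow(fit$history)] + 1e-12)
})

test_that("cross-validation books per-fold entries, stays leak-free and aggregates exactly", {
  cfg <- sim_config(n_subjects = 4, trials_per_subject = 3, duration_ms = 1500,
                    ramp_start_range_ms = c(300, 500),
                    ramp_duration_range_ms = c(300, 500),
                    rest_trial_fraction = 1 / 3, snr_db = 16, seed = 21)
  ds <- simulate_dataset(cfg)
  ncfg <- tiny_net_cfg(); ncfg$in_channels <- 6
  res <- run_cross_validation(ds, ncfg,
                              train_config(max_epochs = 2, n_folds = 2),
                              n_folds = 2)
  expect_equal(nrow(res$fold_metrics), 2)
  expect_setequal(res$fold_metrics$fold, 1:2)
  ## aggregation is the plain arithmetic mean of the per-fold metrics
  expect_equal(res$summary$ode_ms_mean, mean(res$fold_metrics$ode_ms),
               tolerance = 1e-12)
  expect_equal(res$summary$fpr_mean, mean(res$fold_metrics$fpr),
               tolerance = 1e-12)
})
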