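# Scaled-down end-to-end study used by the acceptance checks: 8 subjects x
# 20 trials per noise tier, identical subjects across tiers, 2-fold
# subject-wise cross-validation. Each tier is its own experiment: the
# network and the fixed-threshold baseline are fitted and tuned per fold on
# that tier's training/validation subjects and evaluated on its held-out
# subjects. Sizes (3 s trials, 300-1000 ms onsets, 300-1200 ms rises, 25%
# rest trials, <= 15 epochs with early stopping) are the package's
# scaled-down protocol; see the methods vignette.
acceptance_benchmark <- function(seed = 42, tiers = c("low", "medium", "high")) {
  datasets <- lapply(tiers, function(tier) {
    simulate_dataset(sim_config(
      n_subjects = 8, trials_per_subject = 20, duration_ms = 3000,
      ramp_start_range_ms = c(300, 1000), ramp_duration_range_ms = c(300, 1200),
      noise_tier = tier, rest_trial_fraction = 0.25, seed = seed))
  })
  names(datasets) <- tiers
  detectors <- list(
    detector_fixed(),
    detector_model(net_config(),
                   train_config(max_epochs = 15, early_stop_patience = 5,
                                plateau_patience = 3, seed = seed))
  )
  run_benchmark(datasets, detectors, n_folds = 2, seed = seed)
}

bench_mean <- function(summary, detector, tier, metric) {
  summary[summary$detector == detector & summary$tier == tier,
          paste0(metric, "_mean")]
}
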