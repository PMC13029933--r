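#' Onset detection error and delay
#'
#' `ODE = mean(|t_pred - t_gt|)` and `Delay = mean(max(0, t_pred - t_gt))`
#' over the trials where both a prediction and a ground truth exist. Misses
#' (ground truth present, prediction absent) are excluded here and reported
#' separately as a miss rate, because the error is undefined for an absent
#' prediction.
#'
#' @param preds_ms predicted onsets (ms), `NA` for no detection.
#' @param gts_ms ground-truth onsets (ms), `NA` for rest trials.
#' @return list with `ode_ms`, `delay_ms`, `n_used`, `miss_rate`.
#' @export
#' @examples
#' onset_error_and_delay(c(110, 95), c(100, 100))  # ODE 7.5, Delay 5
onset_error_and_delay <- function(preds_ms, gts_ms) {
  if (length(preds_ms) != length(gts_ms) || !length(preds_ms)) {
    abort("prediction and ground-truth vectors must have equal positive length",
          "slowonset_bad_input")
  }
  act <- !is.na(gts_ms)
  both <- act & !is.na(preds_ms)
  if (!any(both)) {
    abort("no trial has both a prediction and a ground truth: metric undefined",
          "slowonset_undefined_metric")
  }
  d <- preds_ms[both] - gts_ms[both]
  list(ode_ms = mean(abs(d)), delay_ms = mean(pmax(0, d)),
       n_used = sum(both), miss_rate = 1 - sum(both) / sum(act))
}

#' Window-level false positive rate
#'
#' `N_fp / (N_fp + N_tn)` over rest windows, where a rest window counts as
#' a false positive iff the detector's decision marks any of its samples
#' active.
#'
#' @param outcomes logical vector of rest-window outcomes (`TRUE` =
#'   flagged active).
#' @return fraction in `[0, 1]`.
#' @export
false_positive_rate <- function(outcomes) {
  if (!length(outcomes)) {
    abort("no rest windows: FPR undefined", "slowonset_undefined_metric")
  }
  mean(as.logical(outcomes))
}

#' Real-time factor
#'
#' Processing time divided by signal duration; values below 1 mean faster
#' than real time. Hardware dependent, so reported but never compared
#' against fixed expectations.
#'
#' @param t_proc processing time (s).
#' @param t_sig signal duration (s).
#' @return non-negative ratio.
#' @export
real_time_factor <- function(t_proc, t_sig) {
  if (t_sig <= 0) abort("signal duration must be positive", "slowonset_bad_input")
  t_proc / t_sig
}

#' Window-level classification metrics
#'
#' Standard confusion-matrix accuracy, precision and recall over binary
#' window labels.
#'
#' @param predicted,truth binary vectors of equal length.
#' @return list with `accuracy`, `precision`, `recall` (precision/recall are
#'   `NA` when undefined).
#' @export
window_classification_metrics <- function(predicted, truth) {
  if (!length(predicted) || length(predicted) != length(truth)) {
    abort("label vectors must have equal positive length", "slowonset_bad_input")
  }
  p <- as.integer(as.logical(predicted)); t <- as.integer(as.logical(truth))
  tp <- sum(p == 1 & t == 1); tn <- sum(p == 0 & t == 0)
  fp <- sum(p == 1 & t == 0); fn <- sum(p == 0 & t == 1)
  list(accuracy = (tp + tn) / length(p),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

## ---- detector plug-in interface -------------------------------------------

new_detector <- function(name, fit, detect) {
  structure(list(name = name, fit = fit, detect = detect), class = "onset_detector")
}

#' Classical baseline detectors
#'
#' Detector objects for the benchmark harness. `fit` tunes the threshold on
#' the validation trials with [tune_baseline()]; `detect` maps a
#' preprocessed trial to an onset time and a per-sample decision sequence.
#'
#' @param cfg a [baseline_config()] supplying the geometry parameters.
#' @param h_grid threshold multiplier grid for tuning.
#' @return an `onset_detector`.
#' @name baseline_detectors
NULL

baseline_detector <- function(method, cfg, h_grid) {
  new_detector(
    name = paste0(method, "_threshold"),
    fit = function(train_trials, val_trials, seed) {
      tune_baseline(val_trials, method, cfg, h_grid)
    },
    detect = function(state, trial) detect_with_baseline(trial, method, state)
  )
}

#' @rdname baseline_detectors
#' @export
detector_fixed <- function(cfg = baseline_config(), h_grid = seq(0.5, 10, by = 0.5)) {
  baseline_detector("fixed", cfg, h_grid)
}

#' @rdname baseline_detectors
#' @export
detector_adaptive <- function(cfg = baseline_config(), h_grid = seq(0.5, 10, by = 0.5)) {
  baseline_detector("adaptive", cfg, h_grid)
}

#' @rdname baseline_detectors
#' @export
detector_sliding <- function(cfg = baseline_config(), h_grid = seq(0.5, 10, by = 0.5)) {
  baseline_detector("sliding", cfg, h_grid)
}

#' Learned temporal-attention detector
#'
#' Detector object wrapping the full pipeline: `fit` trains the network on
#' the training trials (validation trials drive early stopping) and tunes
#' the decision rule on the validation traces; `detect` stitches the
#' network's confidence trace and applies the continuity criterion.
#'
#' @param net_cfg,train_cfg,decision_cfg pipeline configurations.
#' @param L_ms,S_ms window geometry (ms).
#' @param augment an [augment_spec()] or `NULL`.
#' @return an `onset_detector`.
#' @export
detector_model <- function(net_cfg = net_config(), train_cfg = train_config(),
                           decision_cfg = decision_config(), L_ms = 250,
                           S_ms = 50, augment = NULL) {
  new_detector(
    name = "temporal_attention",
    fit = function(train_trials, val_trials, seed) {
      ## trials arrive preprocessed; window extraction works on the signal.
      ## The network is fitted on trials that contain a rest-to-activation
      ## transition: a trial-normalized activation-free trial is rescaled to
      ## unit variance and is indistinguishable from sustained activity, so
      ## feeding it to the loss only biases the learned boundary upward.
      ## Rest trials still drive decision tuning and false-positive rates.
      prep <- function(trials) {
        trials <- Filter(function(tr) !is.na(tr$onset_ms), trials)
        xs <- list(); tg <- list(); subj <- c()
        for (tr in trials) {
          ws <- segment(tr$signal, tr$fs, L_ms, S_ms)
          ws <- label_windows(ws, tr$onset_ms, tr$offset_ms)
          xs[[length(xs) + 1L]] <- aperm(ws$windows, c(2, 3, 1))
          tg[[length(tg) + 1L]] <- window_targets(ws, tr$onset_ms, tr$offset_ms)
          subj <- c(subj, rep(tr$subject_id, length(ws$start_ms)))
        }
        N <- sum(vapply(xs, function(a) dim(a)[3], numeric(1)))
        d1 <- dim(xs[[1]])
        X <- array(0, dim = c(d1[1], d1[2], N)); at <- 0L
        for (a in xs) { nb <- dim(a)[3]; X[, , at + seq_len(nb)] <- a; at <- at + nb }
        list(X = X, target = do.call(cbind, tg), subject = subj)
      }
      tcfg <- train_cfg
      tcfg$seed <- substream_seed(train_cfg$seed, seed)
      fit <- train_model(prep(train_trials), prep(val_trials), net_cfg, tcfg,
                         augment = augment)
      traces <- lapply(val_trials, function(tr) {
        predict_trial(fit$net, tr, L_ms = L_ms, S_ms = S_ms, preprocessed = TRUE)
      })
      onsets <- vapply(val_trials, function(tr) tr$onset_ms, numeric(1))
      dcfg <- tune_decision(traces, onsets, decision_cfg, L_ms = L_ms, S_ms = S_ms)
      list(net = fit$net, decision = dcfg, history = fit$history)
    },
    detect = function(state, trial) {
      trace <- predict_trial(state$net, trial, L_ms = L_ms, S_ms = S_ms,
                             preprocessed = TRUE)
      pred <- detect_onset(trace, state$decision)
      list(onset_ms = pred$onset_ms,
           active = continuity_decision(trace, state$decision))
    }
  )
}

## preprocess a trial in place (filter + normalize), keeping metadata
preprocess_signal <- function(trial, spec) {
  trial$signal <- normalize_trial(bandpass(trial$signal, trial$fs, spec))
  trial
}

## evaluate a fitted detector on a set of preprocessed trials
evaluate_detector <- function(detector, state, trials, L_ms, S_ms) {
  onsets <- vapply(trials, function(tr) tr$onset_ms, numeric(1))
  preds <- rep(NA_real_, length(trials))
  fp_flags <- logical(0)
  win_pred <- c(); win_true <- c()
  t0 <- proc.time()["elapsed"]
  for (i in seq_along(trials)) {
    out <- detector$detect(state, trials[[i]])
    preds[i] <- out$onset_ms
    ws <- segment(trials[[i]]$signal, trials[[i]]$fs, L_ms, S_ms)
    ws <- label_windows(ws, trials[[i]]$onset_ms, trials[[i]]$offset_ms)
    act <- out$active
    flags <- window_fp_flags(act, trials[[i]]$fs, ws$start_ms, L_ms)
    win_pred <- c(win_pred, as.integer(flags))
    win_true <- c(win_true, ws$labels)
    if (is.na(trials[[i]]$onset_ms)) fp_flags <- c(fp_flags, flags)
    else fp_flags <- c(fp_flags, flags[ws$labels == 0 & ws$start_ms + L_ms <= trials[[i]]$onset_ms])
  }
  t_proc <- proc.time()["elapsed"] - t0
  t_sig <- sum(vapply(trials, function(tr) ncol(tr$signal) / tr$fs, numeric(1)))
  ed <- tryCatch(onset_error_and_delay(preds, onsets),
                 slowonset_undefined_metric = function(e) {
                   list(ode_ms = NA_real_, delay_ms = NA_real_, n_used = 0L,
                        miss_rate = 1)
                 })
  wm <- window_classification_metrics(win_pred, win_true)
  data.frame(ode_ms = ed$ode_ms, delay_ms = ed$delay_ms,
             miss_rate = ed$miss_rate,
             fpr = if (length(fp_flags)) mean(fp_flags) else NA_real_,
             accuracy = wm$accuracy, precision = wm$precision,
             recall = wm$recall,
             rtf = real_time_factor(unname(t_proc), t_sig),
             n_trials = length(trials), n_detected = ed$n_used)
}

## shared fold loop; every condition (tier) is its own experiment: detectors
## are fitted and tuned on that tier's training/validation subjects and
## evaluated on its held-out subjects
benchmark_fold_loop <- function(datasets, detectors, spec,
                                L_ms, S_ms, n_folds, val_subjects_per_fold,
                                seed, verbose = FALSE) {
  prep <- lapply(datasets, function(ds) lapply(ds, preprocess_signal, spec = spec))
  subjects <- dataset_subjects(datasets[[1]])
  folds <- make_subject_folds(subjects, n_folds, seed)
  rows <- list(); states <- list()
  for (f in seq_len(n_folds)) {
    test_subj <- names(folds)[folds == f]
    pool <- setdiff(names(folds), test_subj)
    set.seed(substream_seed(seed, 23L, f))
    pool <- sample(pool)
    val_subj <- pool[seq_len(min(val_subjects_per_fold, length(pool) - 1L))]
    train_subj <- setdiff(pool, val_subj)
    stopifnot(!length(intersect(train_subj, test_subj)),
              !length(intersect(val_subj, test_subj)))
    for (det in detectors) {
      for (tier in names(prep)) {
        if (verbose) message(sprintf("fold %d, tier %s: fitting %s", f, tier, det$name))
        tier_subjects <- dataset_subjects(datasets[[tier]])
        tr_trials <- prep[[tier]][tier_subjects %in% train_subj]
        va_trials <- prep[[tier]][tier_subjects %in% val_subj]
        state <- det$fit(tr_trials, va_trials, f)
        states[[paste(det$name, tier, f, sep = "_")]] <- state
        te_trials <- prep[[tier]][tier_subjects %in% test_subj]
        m <- evaluate_detector(det, state, te_trials, L_ms, S_ms)
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(detector = det$name, tier = tier, fold = f), m)
      }
    }
  }
  list(rows = do.call(rbind, rows), states = states, folds = folds)
}

#' Run the benchmark harness
#'
#' Feeds identical trials to every detector under a subject-wise
#' cross-validation protocol. Every noise tier is treated as its own
#' experiment: detectors are fitted and tuned per fold on that tier's
#' training and validation subjects and evaluated on its held-out
#' subjects, reproducing (at desk scale) the structure of the
#' method-comparison and noise-robustness experiments.
#'
#' @param datasets named list of tier -> dataset (lists of `semg_trial`
#'   with identical subjects); a bare dataset is treated as a single tier
#'   `"eval"`.
#' @param detectors list of detector objects (see [detector_model()],
#'   [detector_fixed()]).
#' @param spec a [filter_spec()].
#' @param L_ms,S_ms window geometry (ms).
#' @param n_folds subject-wise folds; `n_folds = n_subjects` is LOSO.
#' @param val_subjects_per_fold validation subjects carved from each fold's
#'   training side.
#' @param seed integer seed.
#' @param verbose print progress.
#' @return list with `report` (per detector x tier x fold), `summary`
#'   (mean/sd aggregation) and `folds`.
#' @export
run_benchmark <- function(datasets, detectors,
                          spec = filter_spec(), L_ms = 250, S_ms = 50,
                          n_folds = 2, val_subjects_per_fold = 1,
                          seed = 42, verbose = FALSE) {
  if (inherits(datasets, "semg_dataset") ||
      (length(datasets) && inherits(datasets[[1]], "semg_trial"))) {
    datasets <- list(eval = datasets)
  }
  res <- benchmark_fold_loop(datasets, detectors, spec, L_ms,
                             S_ms, n_folds, val_subjects_per_fold, seed,
                             verbose)
  list(report = res$rows, summary = aggregate_report(res$rows),
       folds = res$folds)
}

#' Aggregate a benchmark report across folds
#'
#' @param report the per-fold data frame from [run_benchmark()].
#' @return data frame of per detector x tier means and standard deviations.
#' @export
aggregate_report <- function(report) {
  metrics <- c("ode_ms", "delay_ms", "miss_rate", "fpr", "accuracy",
               "precision", "recall", "rtf")
  keys <- unique(report[, c("detector", "tier")])
  out <- list()
  for (r in seq_len(nrow(keys))) {
    sub <- report[report$detector == keys$detector[r] & report$tier == keys$tier[r], ]
    row <- data.frame(detector = keys$detector[r], tier = keys$tier[r],
                      n_folds = nrow(sub))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(sub) > 1) sd(sub[[m]], na.rm = TRUE) else NA_real_
    }
    out[[r]] <- row
  }
  do.call(rbind, out)
}
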