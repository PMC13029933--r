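#' Training configuration
#'
#' Mini-batch SGD with Nesterov momentum and L2 weight decay; the learning
#' rate is halved when the validation loss plateaus, and training stops
#' early (restoring the best checkpoint) when no improvement is seen for
#' `early_stop_patience` epochs.
#'
#' @param lr initial learning rate.
#' @param momentum Nesterov momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param batch_size windows per mini-batch.
#' @param plateau_factor multiplicative learning-rate drop.
#' @param plateau_patience epochs without improvement before a drop.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param seed seed for shuffling and augmentation draws.
#' @param split train/validation/test fractions for single-run experiments
#'   (cross-validation is the default reporting protocol).
#' @param n_folds folds of the subject-wise cross-validation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr = 0.001, momentum = 0.9, weight_decay = 1e-4,
                         batch_size = 128, plateau_factor = 0.5,
                         plateau_patience = 5, early_stop_patience = 15,
                         max_epochs = 200, seed = 42,
                         split = c(0.70, 0.15, 0.15), n_folds = 5) {
  stopifnot(lr > 0, momentum >= 0, weight_decay >= 0, batch_size >= 1,
            plateau_factor > 0, plateau_factor <= 1, max_epochs >= 0)
  if (abs(sum(split) - 1) > 1e-9) {
    abort("split fractions must sum to 1", "slowonset_bad_config")
  }
  structure(list(lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = batch_size, plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 early_stop_patience = early_stop_patience,
                 max_epochs = max_epochs, seed = seed, split = split,
                 n_folds = n_folds), class = "train_config")
}

#' Subject-wise fold assignment
#'
#' Random near-equal partition of the subjects into `n_folds` disjoint
#' folds, deterministic under the seed. Leave-one-subject-out is the
#' special case `n_folds = length(unique(subject_ids))`.
#'
#' @param subject_ids character vector (possibly with repeats, one per
#'   trial).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return named integer vector: subject -> fold index in `1..n_folds`.
#' @export
make_subject_folds <- function(subject_ids, n_folds, seed = 42) {
  subjects <- sort(unique(subject_ids))
  if (n_folds > length(subjects)) {
    abort(sprintf("%d folds requested for %d subjects", n_folds, length(subjects)),
          "slowonset_bad_config")
  }
  set.seed(substream_seed(seed, 7L))
  perm <- sample(subjects)
  folds <- rep(seq_len(n_folds), length.out = length(subjects))
  stats::setNames(folds[order(match(subjects, perm))], subjects)
}

#' Per-sample binary cross-entropy loss
#'
#' Mean binary cross-entropy between a confidence trace and the per-sample
#' activity indicator; the window-level 50%-rule labels are never used for
#' the loss, only for bookkeeping metrics.
#'
#' @param y confidence values in `[0, 1]` (vector or matrix).
#' @param target binary activity indicator, same shape.
#' @param eps clipping floor for numerical safety.
#' @return non-negative scalar.
#' @export
bce_loss <- function(y, target, eps = 1e-7) {
  if (length(y) != length(target)) abort("length mismatch", "slowonset_bad_input")
  if (any(target != 0 & target != 1)) {
    abort("targets must be binary", "slowonset_bad_input")
  }
  yc <- pmin(pmax(y, eps), 1 - eps)
  -mean(target * log(yc) + (1 - target) * log(1 - yc))
}

## numerically stable BCE from logits
bce_from_logits <- function(z, target) {
  mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
}

#' Assemble a training set of windows and per-sample targets
#'
#' Preprocesses every trial ([preprocess_trial()]) and collects windows,
#' per-sample activity targets, window labels and subject ids.
#'
#' @param trials list of `semg_trial` objects.
#' @param spec a [filter_spec()].
#' @param L_ms,S_ms window geometry (ms).
#' @return list with `X` (`C x L x N` array), `target` (`L x N`), `subject`,
#'   `window_label`, `trial` (index), `start_ms`.
#' @export
make_training_set <- function(trials, spec = filter_spec(), L_ms = 250, S_ms = 50) {
  xs <- list(); tg <- list(); subj <- c(); lab <- c(); tri <- c(); sms <- c()
  for (i in seq_along(trials)) {
    ws <- preprocess_trial(trials[[i]], spec, L_ms, S_ms)
    nw <- length(ws$start_ms)
    if (nw == 0) next
    xs[[length(xs) + 1L]] <- aperm(ws$windows, c(2, 3, 1))   # -> C x L x nw
    tg[[length(tg) + 1L]] <- window_targets(ws, trials[[i]]$onset_ms, trials[[i]]$offset_ms)
    subj <- c(subj, rep(trials[[i]]$subject_id, nw))
    lab <- c(lab, ws$labels)
    tri <- c(tri, rep(i, nw))
    sms <- c(sms, ws$start_ms)
  }
  if (!length(xs)) abort("no usable windows", "slowonset_bad_input")
  d1 <- dim(xs[[1]])
  N <- sum(vapply(xs, function(a) dim(a)[3], numeric(1)))
  X <- array(0, dim = c(d1[1], d1[2], N))
  at <- 0L
  for (a in xs) {
    nb <- dim(a)[3]
    X[, , at + seq_len(nb)] <- a
    at <- at + nb
  }
  list(X = X, target = do.call(cbind, tg), subject = subj,
       window_label = lab, trial = tri, start_ms = sms)
}

validation_loss <- function(net, val_set, chunk = 256L) {
  N <- dim(val_set$X)[3]
  tot <- 0
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(N, s + chunk - 1L)
    cache <- net_forward_cache(val_set$X[, , idx, drop = FALSE], net)
    z <- matrix(cache$logits, nrow = dim(val_set$X)[2])
    tot <- tot + bce_from_logits(z, val_set$target[, idx, drop = FALSE]) * length(idx)
  }
  tot / N
}

#' Train the detection network
#'
#' Mini-batch SGD with Nesterov momentum and weight decay on the per-sample
#' cross-entropy loss. Training and validation sets must be
#' subject-disjoint (asserted - overlap is a leakage error). Amplitude
#' augmentation is applied on the fly to training windows only; validation
#' windows are never augmented.
#'
#' @param train_set,val_set outputs of [make_training_set()].
#' @param net_cfg a [net_config()].
#' @param train_cfg a [train_config()].
#' @param augment an [augment_spec()] or `NULL` to disable augmentation.
#' @param verbose print per-epoch progress.
#' @return list with `net` (best checkpoint), `history` (data frame of
#'   epoch, train_loss, val_loss, lr) and `best_epoch`.
#' @export
train_model <- function(train_set, val_set, net_cfg = net_config(),
                        train_cfg = train_config(), augment = NULL,
                        verbose = FALSE) {
  if (length(intersect(unique(train_set$subject), unique(val_set$subject)))) {
    abort("subject overlap between training and validation sets (leakage)",
          "slowonset_leakage_error")
  }
  net <- init_net(net_cfg)
  vel <- lapply(net$params, function(p) list(W = array(0, dim = dim(p$W)),
                                             b = rep(0, length(p$b))))
  lr <- train_cfg$lr
  mu <- train_cfg$momentum
  wd <- train_cfg$weight_decay
  N <- dim(train_set$X)[3]
  Tlen <- dim(train_set$X)[2]
  best_val <- Inf; best_params <- net$params; best_epoch <- 0L
  plateau_wait <- 0L; stop_wait <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())
  if (train_cfg$max_epochs == 0L) {
    return(list(net = net, history = hist, best_epoch = 0L))
  }
  for (epoch in seq_len(train_cfg$max_epochs)) {
    set.seed(substream_seed(train_cfg$seed, 11L, epoch))
    ord <- sample.int(N)
    ep_loss <- 0
    for (s in seq(1L, N, by = train_cfg$batch_size)) {
      idx <- ord[s:min(N, s + train_cfg$batch_size - 1L)]
      Xb <- train_set$X[, , idx, drop = FALSE]
      if (!is.null(augment)) {
        fire <- runif(length(idx)) < augment$apply_probability
        if (any(fire)) {
          al <- draw_alpha(augment, sum(fire))
          Xb[, , fire] <- Xb[, , fire, drop = FALSE] *
            rep(al, each = dim(Xb)[1] * dim(Xb)[2])
        }
      }
      tb <- train_set$target[, idx, drop = FALSE]
      cache <- net_forward_cache(Xb, net)
      z <- matrix(cache$logits, nrow = Tlen)
      ep_loss <- ep_loss + bce_from_logits(z, tb) * length(idx)
      ## gradient normalization: per-sample BCE summed over the time axis and
      ## averaged over the mini-batch (the usual sequence-labelling scaling);
      ## reported losses stay per-sample means
      dl <- (sigmoid(z) - tb) / length(idx)
      dlogits <- array(dl, dim = c(1, Tlen, length(idx)))
      grads <- net_backward(cache, dlogits, net)
      for (nm in names(net$params)) {
        gW <- grads[[nm]]$dW + wd * net$params[[nm]]$W
        gb <- grads[[nm]]$db
        vel[[nm]]$W <- mu * vel[[nm]]$W + gW
        vel[[nm]]$b <- mu * vel[[nm]]$b + gb
        net$params[[nm]]$W <- net$params[[nm]]$W - lr * (gW + mu * vel[[nm]]$W)
        net$params[[nm]]$b <- net$params[[nm]]$b - lr * (gb + mu * vel[[nm]]$b)
      }
    }
    vloss <- validation_loss(net, val_set)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / N,
                                   val_loss = vloss, lr = lr))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, ep_loss / N, vloss, lr))
    }
    if (vloss < best_val - 1e-6) {
      best_val <- vloss; best_params <- net$params; best_epoch <- epoch
      plateau_wait <- 0L; stop_wait <- 0L
    } else {
      plateau_wait <- plateau_wait + 1L
      stop_wait <- stop_wait + 1L
      if (plateau_wait >= train_cfg$plateau_patience) {
        lr <- lr * train_cfg$plateau_factor
        plateau_wait <- 0L
      }
      if (stop_wait >= train_cfg$early_stop_patience) break
    }
  }
  net$params <- best_params
  list(net = net, history = hist, best_epoch = best_epoch)
}

#' Predict the trial-level confidence trace
#'
#' Preprocesses the trial, runs the network over all windows and stitches
#' the per-window traces into one trial-level confidence curve.
#'
#' @param net an `onset_net`.
#' @param trial a `semg_trial` (raw; preprocessing applied internally unless
#'   `preprocessed = TRUE`).
#' @param spec a [filter_spec()].
#' @param L_ms,S_ms window geometry (ms).
#' @param preprocessed set when `trial$signal` is already filtered and
#'   normalized.
#' @return a [confidence_trace()] on the trial time base.
#' @export
predict_trial <- function(net, trial, spec = filter_spec(), L_ms = 250,
                          S_ms = 50, preprocessed = FALSE) {
  x <- if (preprocessed) trial$signal else
    normalize_trial(bandpass(trial$signal, trial$fs, spec))
  ws <- segment(x, trial$fs, L_ms, S_ms)
  X3 <- aperm(ws$windows, c(2, 3, 1))
  Y <- net_forward_batch(X3, net)
  stitch(lapply(seq_len(ncol(Y)), function(i) Y[, i]), ws$start_ms, trial$fs)
}

#' Subject-wise cross-validation of the full pipeline
#'
#' For each fold: trains on the out-of-fold subjects (carving out validation
#' subjects for early stopping and decision tuning), tunes the decision rule
#' on the validation trials, and evaluates on the held-out fold. No
#' held-out subject ever contributes to training (asserted).
#'
#' @param dataset list of `semg_trial` objects.
#' @param net_cfg,train_cfg,decision_cfg,spec pipeline configurations.
#' @param L_ms,S_ms window geometry (ms).
#' @param n_folds number of subject-wise folds (defaults from `train_cfg`).
#' @param val_subjects_per_fold subjects reserved for validation within each
#'   fold's training side.
#' @param augment an [augment_spec()] or `NULL`.
#' @param verbose print progress.
#' @return list with `fold_metrics` (data frame, one row per fold),
#'   `summary` (mean and sd across folds) and `models`.
#' @export
run_cross_validation <- function(dataset, net_cfg = net_config(),
                                 train_cfg = train_config(),
                                 decision_cfg = decision_config(),
                                 spec = filter_spec(), L_ms = 250, S_ms = 50,
                                 n_folds = train_cfg$n_folds,
                                 val_subjects_per_fold = 1,
                                 augment = NULL, verbose = FALSE) {
  det <- detector_model(net_cfg, train_cfg, decision_cfg, augment = augment)
  res <- benchmark_fold_loop(list(eval = dataset), list(det),
                             spec, L_ms, S_ms, n_folds,
                             val_subjects_per_fold, train_cfg$seed, verbose)
  fm <- res$rows[, setdiff(names(res$rows), c("detector", "tier"))]
  list(fold_metrics = fm, summary = aggregate_report(res$rows), models = res$states)
}
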