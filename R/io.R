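#' Write a trial to disk
#'
#' The trial container is plain text: a tab-separated `samples x channels`
#' table (`<id>.tsv`) plus a JSON sidecar (`<id>.json`) holding subject id,
#' sampling rate, activation interval, noise tier and provenance.
#'
#' @param trial a `semg_trial`.
#' @param dir output directory (created if needed).
#' @param id file stem; defaults to `subject_trialNN` numbering handled by
#'   the caller.
#' @return the file stem, invisibly.
#' @export
write_trial <- function(trial, dir, id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- t(trial$signal)
  colnames(sig) <- sprintf("ch%d", seq_len(ncol(sig)))
  utils::write.table(sig, file.path(dir, paste0(id, ".tsv")), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- trial[c("subject_id", "action_label", "fs", "onset_ms", "offset_ms",
                  "noise_tier", "provenance")]
  jsonlite::write_json(meta, file.path(dir, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(id)
}

#' Read a trial written by [write_trial()]
#'
#' @param dir directory containing the container files.
#' @param id file stem.
#' @return a `semg_trial`.
#' @export
read_trial <- function(dir, id) {
  sig <- unname(as.matrix(utils::read.delim(file.path(dir, paste0(id, ".tsv")))))
  meta <- jsonlite::read_json(file.path(dir, paste0(id, ".json")),
                              simplifyVector = TRUE)
  new_trial(subject_id = meta$subject_id, action_label = meta$action_label,
            fs = meta$fs, signal = t(sig),
            onset_ms = meta$onset_ms %||% NA_real_,
            offset_ms = meta$offset_ms %||% NA_real_,
            noise_tier = meta$noise_tier, provenance = meta$provenance)
}

#' Save a dataset with a CSV manifest
#'
#' One container per trial plus `manifest.csv` (one row per trial: id,
#' subject, onset, tier).
#'
#' @param dataset list of `semg_trial`s.
#' @param dir output directory.
#' @return the manifest data frame, invisibly.
#' @export
save_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  counts <- list()
  for (tr in dataset) {
    counts[[tr$subject_id]] <- (counts[[tr$subject_id]] %||% 0L) + 1L
    id <- sprintf("%s_trial%02d", tr$subject_id, counts[[tr$subject_id]])
    write_trial(tr, dir, id)
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, subject_id = tr$subject_id, action_label = tr$action_label,
      fs = tr$fs, n_channels = nrow(tr$signal), n_samples = ncol(tr$signal),
      onset_ms = tr$onset_ms, offset_ms = tr$offset_ms,
      noise_tier = tr$noise_tier)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Load a dataset saved by [save_dataset()]
#'
#' @param dir dataset directory with `manifest.csv`.
#' @return a list of `semg_trial`s (class `semg_dataset`).
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  trials <- lapply(manifest$id, function(id) read_trial(dir, id))
  structure(trials, class = c("semg_dataset", "list"))
}

config_defaults <- function() {
  list(
    sim = sim_config(),
    filter = filter_spec(),
    window = list(L_ms = 250, S_ms = 50),
    augment = augment_spec(),
    net = net_config(),
    train = train_config(),
    decision = decision_config(),
    baseline = baseline_config(),
    benchmark = list(n_folds = 2, val_subjects_per_fold = 1),
    seed = 42
  )
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML file of nested blocks (`sim`, `filter`, `window`,
#' `augment`, `net`, `train`, `decision`, `baseline`, `benchmark`, `seed`),
#' fills documented defaults, rejects unknown keys and re-validates every
#' block through its constructor.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a named list of validated configuration objects.
#' @export
load_config <- function(path = NULL) {
  defaults <- config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort(sprintf("unknown config block(s): %s", paste(unknown, collapse = ", ")),
          "slowonset_bad_config")
  }
  ctors <- list(sim = sim_config, filter = filter_spec, augment = augment_spec,
                net = net_config, train = train_config,
                decision = decision_config, baseline = baseline_config)
  out <- defaults
  for (block in names(user)) {
    if (block == "seed") { out$seed <- user$seed; next }
    if (block %in% c("window", "benchmark")) {
      extra <- setdiff(names(user[[block]]), names(defaults[[block]]))
      if (length(extra)) {
        abort(sprintf("unknown key(s) in `%s`: %s", block,
                      paste(extra, collapse = ", ")), "slowonset_bad_config")
      }
      out[[block]][names(user[[block]])] <- user[[block]]
      next
    }
    ctor <- ctors[[block]]
    known <- names(formals(ctor))
    extra <- setdiff(names(user[[block]]), known)
    if (length(extra)) {
      abort(sprintf("unknown key(s) in `%s`: %s", block,
                    paste(extra, collapse = ", ")), "slowonset_bad_config")
    }
    args <- unclass(defaults[[block]])[intersect(names(unclass(defaults[[block]])), known)]
    args[names(user[[block]])] <- user[[block]]
    out[[block]] <- do.call(ctor, args)
  }
  out
}

#' Write the fully resolved configuration next to run outputs
#'
#' Every CLI run records its resolved configuration and seed so output
#' directories are self-describing.
#'
#' @param config a [load_config()] result.
#' @param dir output directory.
#' @return the file path, invisibly.
#' @export
write_resolved_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(lapply(config, function(b) if (is.list(b)) unclass(b) else b), path)
  invisible(path)
}
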