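#' Construct and validate a trial table
#'
#' One row per trial: word label, cue modality, the onset time of every task
#' phase (trial-relative seconds, 0 at ITI onset), audio-cue onset latency
#' for auditory trials, and an error flag. Trials on which the participant
#' spoke during the internal-speech phase or vocalized the wrong word are
#' kept in the table (and in any archive) and removed only at analysis time
#' by [exclude_error_trials()].
#'
#' @param df A data.frame with columns `trial_id`, `session_id`, `word`,
#'   `cue_modality`, `onset_<phase>` for every phase in `config`,
#'   `audio_onset` (NA on written-cue trials) and `error_kind` (one of
#'   `"none"`, `"spoke_during_internal"`, `"wrong_word_vocalized"`).
#' @param config The [task_config()] the trials were recorded under.
#' @return The validated data.frame with class `trial_table`.
#' @export
trial_table <- function(df, config) {
  stopifnot(inherits(config, "task_config"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  onset_cols <- paste0("onset_", config$phase_names)
  need <- c("trial_id", "session_id", "word", "cue_modality",
            onset_cols, "audio_onset", "error_kind")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trial_table: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$trial_id))
    stop("trial_table: duplicated trial_id")
  bad_word <- setdiff(unique(df$word), config$words)
  if (length(bad_word))
    stop("trial_table: word not in config.words: ",
         paste(bad_word, collapse = ", "))
  bad_mod <- setdiff(unique(df$cue_modality), config$cue_modalities)
  if (length(bad_mod))
    stop("trial_table: cue_modality not in config: ",
         paste(bad_mod, collapse = ", "))
  ok_err <- c("none", "spoke_during_internal", "wrong_word_vocalized")
  if (!all(df$error_kind %in% ok_err))
    stop("trial_table: error_kind must be one of ",
         paste(ok_err, collapse = ", "))
  ons <- as.matrix(df[, onset_cols])
  if (any(!is.finite(ons))) stop("trial_table: non-finite phase onsets")
  if (ncol(ons) > 1 && any(t(apply(ons, 1, diff)) <= 0))
    stop("trial_table: phase_onsets must be strictly increasing")
  aud <- df$cue_modality == "auditory"
  if (any(aud & !is.finite(df$audio_onset)))
    stop("trial_table: audio_onset missing on auditory trial(s)")
  df$trial_id <- as.integer(df$trial_id)
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Per-condition repetition counts
#'
#' @param trials A [trial_table()].
#' @return A data.frame with columns `session_id`, `word`, `cue_modality`,
#'   `n` giving the repetition count of every observed condition cell.
#' @export
repetition_counts <- function(trials) {
  agg <- stats::aggregate(
    list(n = trials$trial_id),
    by = list(session_id = trials$session_id, word = trials$word,
              cue_modality = trials$cue_modality),
    FUN = length)
  agg[order(agg$session_id, agg$word, agg$cue_modality), , drop = FALSE]
}

#' Construct and validate per-unit spike data
#'
#' Spike timestamps are stored per unit and per trial, in seconds relative
#' to trial start. The unit roster (with its cortical-area label, SMG or
#' S1) must be identical across all trials of a session; timestamps must be
#' non-decreasing and lie within the trial.
#'
#' @param units Data.frame with columns `unit_id` and `area`
#'   (`"SMG"` or `"S1"`).
#' @param spikes Named list (by `unit_id`), each element a named list (by
#'   `trial_id` as character) of numeric spike-time vectors.
#' @param trials The matching [trial_table()].
#' @param config The [task_config()] (for the trial duration bound).
#' @return An object of class `spike_data`.
#' @export
spike_data <- function(units, spikes, trials, config) {
  stopifnot(inherits(config, "task_config"))
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  if (!all(c("unit_id", "area") %in% names(units)))
    stop("spike_data: units needs unit_id and area columns")
  if (anyDuplicated(units$unit_id)) stop("spike_data: duplicated unit_id")
  if (!all(units$area %in% c("SMG", "S1")))
    stop("spike_data: area must be SMG or S1")
  units$unit_id <- as.character(units$unit_id)
  dur <- trial_duration(config)
  trial_ids <- as.character(trials$trial_id)
  if (!setequal(names(spikes), units$unit_id))
    stop("spike_data: spike list names must match unit roster")
  for (u in units$unit_id) {
    if (!setequal(names(spikes[[u]]), trial_ids))
      stop("spike_data: unit ", u, " does not cover all trials")
    for (tr in trial_ids) {
      st <- spikes[[u]][[tr]]
      if (length(st)) {
        if (is.unsorted(st))
          stop("spike_data: unsorted spike times for unit ", u,
               " trial ", tr)
        if (st[1] < 0 || st[length(st)] > dur + 1e-9)
          stop("spike_data: spike time out of [0, ", dur,
               "] for unit ", u, " trial ", tr)
      }
    }
  }
  structure(list(units = units,
                 spikes = spikes[units$unit_id],
                 trial_duration = dur),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  n_sp <- sum(vapply(x$spikes, function(u) sum(lengths(u)), 0))
  cat(sprintf("Spike data: %d units (%d SMG, %d S1), %d trials, %d spikes\n",
              nrow(x$units), sum(x$units$area == "SMG"),
              sum(x$units$area == "S1"),
              length(x$spikes[[1]]), n_sp))
  invisible(x)
}

SESSION_SCHEMA_VERSION <- "1.0"

#' Write a session archive
#'
#' Serializes a session to a self-describing directory of plain-text files:
#' `config.json` (task configuration plus schema version), `trials.csv`
#' (the trial table), `units.csv` (unit roster) and `spikes.csv` (long
#' format: `unit_id`, `trial_id`, `spike_time`). [read_session()] inverts
#' the archive bit-exactly for integers and labels and to full double
#' precision for times.
#'
#' @param config A [task_config()].
#' @param trials A [trial_table()].
#' @param spikes A [spike_data()].
#' @param path Directory to create (must not be an existing non-directory).
#' @return `path`, invisibly.
#' @export
write_session <- function(config, trials, spikes, path) {
  trials <- trial_table(as.data.frame(trials), config)  # re-validate
  if (file.exists(path) && !dir.exists(path))
    stop("write_session: path exists and is not a directory: ", path)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  cfg <- unclass(config)
  cfg$phase_durations <- as.numeric(cfg$phase_durations)
  cfg$schema_version <- SESSION_SCHEMA_VERSION
  jsonlite::write_json(cfg, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(trials), file.path(path, "trials.csv"),
                   row.names = FALSE)
  utils::write.csv(spikes$units, file.path(path, "units.csv"),
                   row.names = FALSE)
  long <- do.call(rbind, lapply(spikes$units$unit_id, function(u) {
    per_tr <- spikes$spikes[[u]]
    n <- lengths(per_tr)
    data.frame(unit_id = rep(u, sum(n)),
               trial_id = rep(as.integer(names(per_tr)), n),
               spike_time = unlist(per_tr, use.names = FALSE))
  }))
  if (is.null(long))
    long <- data.frame(unit_id = character(), trial_id = integer(),
                       spike_time = numeric())
  # full double precision survives the text round trip via format(digits=17)
  long$spike_time <- format(long$spike_time, digits = 17, trim = TRUE,
                            scientific = FALSE)
  utils::write.csv(long, file.path(path, "spikes.csv"), row.names = FALSE)
  invisible(path)
}

#' Read a session archive
#'
#' @param path Directory written by [write_session()] (or conforming to the
#'   documented CSV+JSON layout).
#' @return A list with elements `config`, `trials`, `spikes`.
#' @export
read_session <- function(path) {
  cfg_file <- file.path(path, "config.json")
  if (!file.exists(cfg_file)) stop("read_session: missing config.json")
  cfg <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
  ver <- cfg$schema_version
  if (is.null(ver) || !identical(ver, SESSION_SCHEMA_VERSION))
    stop("read_session: schema version mismatch (found ",
         if (is.null(ver)) "none" else ver, ", expected ",
         SESSION_SCHEMA_VERSION, ")")
  config <- task_config(words = cfg$words, phase_names = cfg$phase_names,
                        phase_durations = cfg$phase_durations,
                        cue_modalities = cfg$cue_modalities,
                        bin_width = cfg$bin_width,
                        kernel_width = cfg$kernel_width,
                        audio_onset_range = cfg$audio_onset_range)
  tdf <- utils::read.csv(file.path(path, "trials.csv"),
                         stringsAsFactors = FALSE)
  onset_cols <- paste0("onset_", config$phase_names)
  miss <- setdiff(c(onset_cols, "trial_id", "word", "cue_modality",
                    "error_kind"), names(tdf))
  if (length(miss))
    stop("read_session: trials.csv missing column(s): ",
         paste(miss, collapse = ", "))
  if (!"audio_onset" %in% names(tdf)) tdf$audio_onset <- NA_real_
  if (!"session_id" %in% names(tdf)) tdf$session_id <- basename(path)
  tdf$session_id <- as.character(tdf$session_id)
  trials <- trial_table(tdf, config)
  units <- utils::read.csv(file.path(path, "units.csv"),
                           stringsAsFactors = FALSE)
  if (!all(c("unit_id", "area") %in% names(units)))
    stop("read_session: units.csv missing unit_id/area column")
  units$unit_id <- as.character(units$unit_id)
  long <- utils::read.csv(file.path(path, "spikes.csv"),
                          stringsAsFactors = FALSE)
  if (!all(c("unit_id", "trial_id", "spike_time") %in% names(long)))
    stop("read_session: spikes.csv missing column(s)")
  long$unit_id <- as.character(long$unit_id)
  long$spike_time <- as.numeric(long$spike_time)
  trial_ids <- as.character(trials$trial_id)
  spl <- split(long[, c("trial_id", "spike_time")], long$unit_id)
  spikes <- lapply(units$unit_id, function(u) {
    per <- stats::setNames(
      rep(list(numeric(0)), length(trial_ids)), trial_ids)
    if (u %in% names(spl)) {
      s2 <- split(spl[[u]]$spike_time, as.character(spl[[u]]$trial_id))
      per[names(s2)] <- s2
    }
    per
  })
  names(spikes) <- units$unit_id
  list(config = config, trials = trials,
       spikes = spike_data(units, spikes, trials, config))
}

#' Remove error trials before analysis
#'
#' Drops trials whose `error_kind` is not `"none"` — the participant spoke
#' aloud during the internal-speech phase, or vocalized the wrong word —
#' from both the trial table and the spike data, and reports how many
#' trials of each kind were removed. Idempotent.
#'
#' @param trials A [trial_table()].
#' @param spikes The matching [spike_data()].
#' @return List with `trials`, `spikes` (filtered) and `report` (named
#'   integer vector of removed counts per error kind, plus `retained`).
#' @export
exclude_error_trials <- function(trials, spikes) {
  keep <- trials$error_kind == "none"
  kinds <- c("spoke_during_internal", "wrong_word_vocalized")
  report <- vapply(kinds, function(k) sum(trials$error_kind == k), 0L)
  report <- c(report, retained = sum(keep))
  out_trials <- trials[keep, , drop = FALSE]
  keep_ids <- as.character(out_trials$trial_id)
  out_spikes <- spikes
  out_spikes$spikes <- lapply(spikes$spikes, function(u) u[keep_ids])
  if (!any(keep))
    warning("exclude_error_trials: no trials retained")
  list(trials = out_trials, spikes = out_spikes, report = report)
}
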