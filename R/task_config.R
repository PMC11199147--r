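#' Task configuration for a word-production session
#'
#' Describes the fixed structure of the cued word-production task: the word
#' vocabulary, the six trial phases (ITI, cue, D1, internal, D2, speech) with
#' their durations, the cue modalities in use, and the temporal resolution
#' used downstream (bin width for spike counting, Gaussian kernel width for
#' smoothing). Defaults reproduce the task as run: a 2-s inter-trial
#' interval, a 1.5-s cue, two 0.5-s delays flanking a 1.5-s internal-speech
#' phase, and a 1.5-s vocalized-speech phase; six lexical words plus two
#' pseudowords; 50-ms bins and a 50-ms smoothing kernel; auditory cue onset
#' falling 200-650 ms into the cue phase.
#'
#' @param words Character vector of word labels (length >= 2).
#' @param phase_names Character vector of phase names, in trial order.
#' @param phase_durations Numeric vector of phase durations in seconds,
#'   parallel to `phase_names`; all strictly positive.
#' @param cue_modalities Subset of `c("auditory", "written")`.
#' @param bin_width Spike-count bin width in seconds.
#' @param kernel_width Gaussian smoothing kernel standard deviation in
#'   seconds.
#' @param audio_onset_range Length-2 numeric, the (min, max) latency of
#'   audio onset after cue-phase start, seconds.
#' @return An object of class `task_config`.
#' @examples
#' cfg <- task_config()
#' phase_onsets(cfg)
#' @export
task_config <- function(words = c("battlefield", "cowboy", "python", "spoon",
                                  "swimming", "telephone", "bindip", "nifzig"),
                        phase_names = c("ITI", "cue", "D1", "internal",
                                        "D2", "speech"),
                        phase_durations = c(2.0, 1.5, 0.5, 1.5, 0.5, 1.5),
                        cue_modalities = c("auditory", "written"),
                        bin_width = 0.05,
                        kernel_width = 0.05,
                        audio_onset_range = c(0.200, 0.650)) {
  words <- as.character(words)
  if (length(words) < 2) stop("task_config: need at least 2 words")
  if (anyDuplicated(words)) stop("task_config: duplicated word labels")
  if (length(phase_names) != length(phase_durations))
    stop("task_config: phase_names and phase_durations lengths differ")
  phase_durations <- as.numeric(phase_durations)
  if (any(!is.finite(phase_durations)) || any(phase_durations <= 0))
    stop("task_config: all phase durations must be positive")
  if (!all(cue_modalities %in% c("auditory", "written")) ||
      length(cue_modalities) < 1)
    stop("task_config: cue_modalities must be a subset of auditory/written")
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("task_config: bin_width must be positive")
  if (!is.numeric(kernel_width) || kernel_width <= 0)
    stop("task_config: kernel_width must be positive")
  if (length(audio_onset_range) != 2 || diff(audio_onset_range) < 0 ||
      audio_onset_range[1] < 0)
    stop("task_config: audio_onset_range must be an increasing pair >= 0")
  # each phase must hold a whole number of bins (to within one part in 1e6)
  nb <- phase_durations / bin_width
  if (any(abs(nb - round(nb)) > 1e-6))
    stop("task_config: bin_width must divide each phase duration")
  structure(
    list(words = words,
         phase_names = as.character(phase_names),
         phase_durations = stats::setNames(phase_durations, phase_names),
         cue_modalities = as.character(cue_modalities),
         bin_width = bin_width,
         kernel_width = kernel_width,
         audio_onset_range = as.numeric(audio_onset_range)),
    class = "task_config")
}

#' Phase onset times of a task configuration
#'
#' @param config A [task_config()].
#' @return Named numeric vector of phase onsets in seconds, trial-relative
#'   (0 at ITI onset).
#' @export
phase_onsets <- function(config) {
  stopifnot(inherits(config, "task_config"))
  on <- cumsum(c(0, utils::head(config$phase_durations, -1)))
  stats::setNames(on, config$phase_names)
}

#' Total trial duration in seconds
#' @param config A [task_config()].
#' @return Scalar, the sum of phase durations.
#' @export
trial_duration <- function(config) {
  stopifnot(inherits(config, "task_config"))
  sum(config$phase_durations)
}

#' Indices of time bins belonging to each phase
#'
#' Bins are half-open `[edge_b, edge_{b+1})`, 0-anchored at trial start; a
#' phase owns every bin whose left edge lies in `[onset, offset)`.
#'
#' @param config A [task_config()].
#' @return Named list of integer bin-index vectors, one per phase.
#' @export
phase_bins <- function(config) {
  stopifnot(inherits(config, "task_config"))
  bw <- config$bin_width
  n_bins <- round(trial_duration(config) / bw)
  left <- (seq_len(n_bins) - 1L) * bw
  on <- phase_onsets(config)
  off <- on + config$phase_durations
  out <- lapply(seq_along(on), function(i) {
    which(left >= on[i] - 1e-9 & left < off[i] - 1e-9)
  })
  stats::setNames(out, config$phase_names)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Task configuration\n")
  cat("  words (", length(x$words), "): ",
      paste(x$words, collapse = ", "), "\n", sep = "")
  cat("  phases: ",
      paste(sprintf("%s (%g s)", x$phase_names, x$phase_durations),
            collapse = ", "), "\n", sep = "")
  cat("  cue modalities: ", paste(x$cue_modalities, collapse = ", "), "\n",
      sep = "")
  cat(sprintf("  bin width %g s, kernel width %g s, audio onset %g-%g s\n",
              x$bin_width, x$kernel_width,
              x$audio_onset_range[1], x$audio_onset_range[2]))
  invisible(x)
}
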