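#' Specification of a synthetic neural population
#'
#' Parameterizes the ground-truth population from which synthetic sessions
#' are simulated. Units are Poisson spikers whose rate is piecewise
#' constant over trial phases: a baseline plus, for tuned units, an
#' additive word-by-phase gain (spikes/s), plus an additive cue-modality
#' gain during the cue phase. SMG-like units may be word-selective in any
#' designated phase; S1-like units are word-agnostic — their gain is the
#' same for every word and nonzero only during vocalized speech, emulating
#' somatosensory activation that carries no word identity.
#'
#' @param n_units Number of units.
#' @param area `"SMG"` or `"S1"` (a population is homogeneous; mix
#'   populations by concatenation).
#' @param tuned_fraction Named numeric vector over phases: the fraction of
#'   units carrying word-selective gain in that phase. Ignored for S1.
#' @param effect_mean,effect_sd Mean and SD of the absolute gain
#'   (spikes/s) drawn for each selected word of a tuned unit.
#' @param baseline_mean,baseline_sd Mean and SD of the gamma-distributed
#'   baseline rate (spikes/s).
#' @param modality_sd SD of the additive cue-modality gain (spikes/s)
#'   applied during the cue phase (auditory vs written); 0 disables it.
#' @param word_prob Probability that a given word is selected (receives
#'   gain) for a tuned unit in a tuned phase; at least one word is always
#'   selected.
#' @param latency Response-onset lag (s) of the gain within each phase.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_units = 60,
                            area = c("SMG", "S1"),
                            tuned_fraction = c(ITI = 0, cue = 0.3, D1 = 0,
                                               internal = 0.3, D2 = 0,
                                               speech = 0.5),
                            effect_mean = 4, effect_sd = 1.5,
                            baseline_mean = 5, baseline_sd = 2,
                            modality_sd = 0,
                            word_prob = 0.5,
                            latency = 0) {
  area <- match.arg(area)
  if (n_units < 1) stop("population_spec: n_units must be >= 1")
  if (any(tuned_fraction < 0 | tuned_fraction > 1))
    stop("population_spec: tuned_fraction values must lie in [0, 1]")
  if (baseline_mean < 0 || baseline_sd < 0)
    stop("population_spec: baseline distribution parameters must be >= 0")
  if (latency < 0) stop("population_spec: latency must be >= 0")
  structure(list(n_units = as.integer(n_units), area = area,
                 tuned_fraction = tuned_fraction,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 modality_sd = modality_sd, word_prob = word_prob,
                 latency = latency),
            class = "population_spec")
}

#' Draw a ground-truth population
#'
#' Samples per-unit baselines and additive gain structure from a
#' [population_spec()]. For SMG-like populations, `round(n_units *
#' tuned_fraction[phase])` units are selected (uniformly, per phase) to
#' carry word gain in that phase; each selected unit receives an absolute
#' gain `|N(effect_mean, effect_sd)|` on a random subset of words. For
#' S1-like populations the same count of units receives a single
#' word-agnostic gain in the speech phase only.
#'
#' @param spec A [population_spec()].
#' @param config A [task_config()].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return List of per-unit ground-truth records, class
#'   `population_truth`. Each record has `unit_id`, `area`,
#'   `baseline_rate`, `gain` (W x P matrix, spikes/s), `modality_gain`
#'   (named vector over cue modalities) and `latency`.
#' @export
sample_population <- function(spec, config = task_config(), seed = 1L) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(config, "task_config"))
  rs <- local_rng(seed)
  W <- length(config$words)
  P <- length(config$phase_names)
  tf <- rep(0, P)
  names(tf) <- config$phase_names
  common <- intersect(names(spec$tuned_fraction), config$phase_names)
  tf[common] <- spec$tuned_fraction[common]
  if (spec$area == "S1") {
    tf[] <- 0
    tf["speech"] <- max(spec$tuned_fraction["speech"], 0, na.rm = TRUE)
    if (is.na(tf["speech"])) tf["speech"] <- 0
  }
  baselines <- if (spec$baseline_sd == 0) {
    rep(spec$baseline_mean, spec$n_units)
  } else {
    shape <- (spec$baseline_mean / spec$baseline_sd)^2
    rate <- spec$baseline_mean / spec$baseline_sd^2
    stats::rgamma(spec$n_units, shape = shape, rate = rate)
  }
  sel <- matrix(FALSE, spec$n_units, P,
                dimnames = list(NULL, config$phase_names))
  for (p in config$phase_names) {
    k <- round(spec$n_units * tf[p])
    if (k > 0) sel[sample.int(spec$n_units, k), p] <- TRUE
  }
  pop <- vector("list", spec$n_units)
  for (u in seq_len(spec$n_units)) {
    gain <- matrix(0, W, P, dimnames = list(config$words,
                                            config$phase_names))
    for (p in config$phase_names) {
      if (!sel[u, p]) next
      amp <- abs(stats::rnorm(W, spec$effect_mean, spec$effect_sd))
      if (spec$area == "S1") {
        gain[, p] <- amp[1]          # word-agnostic: identical for all words
      } else {
        pick <- stats::runif(W) < spec$word_prob
        if (!any(pick)) pick[sample.int(W, 1)] <- TRUE
        gain[pick, p] <- amp[pick]
      }
    }
    mg <- stats::setNames(rep(0, length(config$cue_modalities)),
                          config$cue_modalities)
    if (spec$modality_sd > 0 && spec$area == "SMG")
      mg[] <- stats::rnorm(length(mg), 0, spec$modality_sd)
    pop[[u]] <- list(unit_id = sprintf("%s_%03d", spec$area, u),
                     area = spec$area,
                     baseline_rate = baselines[u],
                     gain = gain,
                     modality_gain = mg,
                     latency = spec$latency)
  }
  structure(pop, class = "population_truth")
}

# Per-trial, per-unit piecewise-constant rate segments.
# Returns data.frame(start, end, rate) covering [0, trial duration).
unit_rate_segments <- function(unit, word, modality, audio_onset, config) {
  on <- phase_onsets(config)
  off <- on + config$phase_durations
  segs <- list()
  for (p in config$phase_names) {
    base <- unit$baseline_rate
    g <- unit$gain[word, p]
    if (p == "cue") g <- g + unit$modality_gain[[modality]]
    gain_start <- on[[p]] + unit$latency
    if (p == "cue" && identical(modality, "auditory") &&
        is.finite(audio_onset))
      gain_start <- on[[p]] + audio_onset + unit$latency
    gain_start <- min(gain_start, off[[p]])
    if (gain_start > on[[p]])
      segs[[length(segs) + 1L]] <-
        data.frame(start = on[[p]], end = gain_start, rate = base)
    if (gain_start < off[[p]])
      segs[[length(segs) + 1L]] <-
        data.frame(start = gain_start, end = off[[p]], rate = base + g)
  }
  do.call(rbind, segs)
}

#' Simulate a synthetic session
#'
#' Generates `n_reps` repetitions of every word under every requested cue
#' modality, in one seeded random order, and draws each unit's spikes from
#' an inhomogeneous (piecewise-constant-rate) Poisson process: baseline
#' rate everywhere, plus the unit's word-by-phase gain within each phase,
#' plus its cue-modality gain during the cue phase. On auditory-cue trials
#' the audio onset is drawn uniformly from `config$audio_onset_range` and
#' cue-phase gains begin at audio onset. Negative summed rates are clipped
#' to zero and the clip events counted.
#'
#' @param pop A [sample_population()] result.
#' @param config A [task_config()].
#' @param n_reps Repetitions per word per modality.
#' @param cue_modalities Modalities to run (default: those in `config`).
#' @param seed Integer seed.
#' @param session_id Session label stored in the trial table.
#' @return List with `trials` ([trial_table()]), `spikes`
#'   ([spike_data()]), `truth` (the population, plus `n_rate_clips`).
#' @export
simulate_session <- function(pop, config = task_config(), n_reps = 8,
                             cue_modalities = config$cue_modalities,
                             seed = 1L, session_id = "sim") {
  stopifnot(inherits(pop, "population_truth"),
            inherits(config, "task_config"), n_reps >= 1)
  rs <- local_rng(seed)
  conds <- expand.grid(word = config$words, cue_modality = cue_modalities,
                       rep = seq_len(n_reps), stringsAsFactors = FALSE)
  conds <- conds[sample.int(nrow(conds)), , drop = FALSE]  # one permutation
  n_tr <- nrow(conds)
  on <- phase_onsets(config)
  tdf <- data.frame(trial_id = seq_len(n_tr),
                    session_id = session_id,
                    word = conds$word,
                    cue_modality = conds$cue_modality,
                    stringsAsFactors = FALSE)
  for (p in config$phase_names) tdf[[paste0("onset_", p)]] <- on[[p]]
  tdf$audio_onset <- ifelse(
    tdf$cue_modality == "auditory",
    stats::runif(n_tr, config$audio_onset_range[1],
                 config$audio_onset_range[2]),
    NA_real_)
  tdf$error_kind <- "none"
  trials <- trial_table(tdf, config)

  n_clips <- 0L
  spikes <- vector("list", length(pop))
  names(spikes) <- vapply(pop, `[[`, "", "unit_id")
  for (u in seq_along(pop)) {
    per_trial <- vector("list", n_tr)
    for (t in seq_len(n_tr)) {
      segs <- unit_rate_segments(pop[[u]], trials$word[t],
                                 trials$cue_modality[t],
                                 trials$audio_onset[t], config)
      clip <- segs$rate < 0
      if (any(clip)) {
        n_clips <- n_clips + sum(clip)
        segs$rate[clip] <- 0
      }
      times <- numeric(0)
      for (s in seq_len(nrow(segs))) {
        len <- segs$end[s] - segs$start[s]
        lam <- segs$rate[s] * len
        if (lam > 0) {
          k <- stats::rpois(1, lam)
          if (k > 0)
            times <- c(times,
                       segs$start[s] + stats::runif(k, 0, len))
        }
      }
      per_trial[[t]] <- sort(times)
    }
    names(per_trial) <- as.character(trials$trial_id)
    spikes[[u]] <- per_trial
  }
  units <- data.frame(unit_id = names(spikes),
                      area = vapply(pop, `[[`, "", "area"),
                      stringsAsFactors = FALSE)
  truth <- pop
  attr(truth, "n_rate_clips") <- n_clips
  list(trials = trials,
       spikes = spike_data(units, spikes, trials, config),
       truth = truth)
}

#' Flag error trials at random
#'
#' Marks each trial, independently and reproducibly, as
#' `spoke_during_internal` with probability `p_spoke` or (otherwise) as
#' `wrong_word_vocalized` with probability `p_wrong`, emulating the
#' participant errors that are excluded from analysis.
#'
#' @param trials A [trial_table()].
#' @param p_spoke,p_wrong Per-trial error probabilities in `[0, 1]`.
#' @param seed Integer seed.
#' @return The trial table with `error_kind` updated.
#' @export
inject_errors <- function(trials, p_spoke = 0, p_wrong = 0, seed = 1L) {
  if (p_spoke < 0 || p_spoke > 1 || p_wrong < 0 || p_wrong > 1)
    stop("inject_errors: probabilities must lie in [0, 1]")
  rs <- local_rng(seed)
  n <- nrow(trials)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  kind <- rep("none", n)
  kind[u1 < p_spoke] <- "spoke_during_internal"
  kind[u1 >= p_spoke & u2 < p_wrong] <- "wrong_word_vocalized"
  trials$error_kind <- kind
  trials
}
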