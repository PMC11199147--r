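#' Bin spike counts into instantaneous firing rates
#'
#' Counts spikes in uniform half-open bins `[edge_b, edge_{b+1})` of width
#' `config$bin_width` (50 ms by default) and divides by the bin width,
#' giving unsmoothed instantaneous firing rates in spikes/s.
#'
#' @param spikes A [spike_data()].
#' @param trials The matching [trial_table()].
#' @param config A [task_config()].
#' @return An object of class `rate_tensor`: list with `values`
#'   (trials x units x bins array, spikes/s), `bin_edges`, `phase_bins`
#'   (bin indices per phase), `alignment` (`"trial_start"`), `smoothed`,
#'   `kernel_width`, `trial_ids`, `unit_ids`.
#' @export
bin_spike_counts <- function(spikes, trials, config) {
  stopifnot(inherits(spikes, "spike_data"), inherits(config, "task_config"))
  bw <- config$bin_width
  dur <- trial_duration(config)
  n_bins <- round(dur / bw)
  edges <- seq(0, by = bw, length.out = n_bins + 1L)
  trial_ids <- as.character(trials$trial_id)
  unit_ids <- spikes$units$unit_id
  vals <- array(0, dim = c(length(trial_ids), length(unit_ids), n_bins),
                dimnames = list(trial_ids, unit_ids, NULL))
  for (u in seq_along(unit_ids)) {
    per <- spikes$spikes[[unit_ids[u]]]
    for (t in seq_along(trial_ids)) {
      st <- per[[trial_ids[t]]]
      if (!length(st)) next
      if (any(st < 0 | st > dur + 1e-9))
        stop("bin_spike_counts: spike outside trial bounds for unit ",
             unit_ids[u], " trial ", trial_ids[t])
      idx <- findInterval(st, edges)       # edges[i] <= t < edges[i+1]
      idx[idx > n_bins] <- n_bins          # a spike exactly at trial end
      vals[t, u, ] <- tabulate(idx, nbins = n_bins) / bw
    }
  }
  structure(list(values = vals, bin_edges = edges,
                 phase_bins = phase_bins(config),
                 alignment = "trial_start",
                 smoothed = FALSE, kernel_width = NA_real_,
                 trial_ids = trials$trial_id, unit_ids = unit_ids),
            class = "rate_tensor")
}

# Smoothing matrix: rows are a normalized Gaussian (sd = sigma_bins,
# truncated at +/- 4 sd) with reflection padding at the series ends, so a
# constant series is reproduced exactly.
gaussian_smoother <- function(n_bins, sigma_bins) {
  h <- max(1L, ceiling(4 * sigma_bins))
  k <- stats::dnorm(seq(-h, h), sd = sigma_bins)
  k <- k / sum(k)
  S <- matrix(0, n_bins, n_bins)
  for (i in seq_len(n_bins)) {
    j <- (i - h):(i + h)
    # reflect indices about the boundaries (symmetric padding)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n_bins, 2L * n_bins + 1L - j, j)
    for (m in seq_along(j)) S[i, j[m]] <- S[i, j[m]] + k[m]
  }
  S
}

#' Smooth a rate tensor with a Gaussian kernel
#'
#' Convolves each trial-by-unit rate series with a normalized Gaussian
#' kernel whose standard deviation is `kernel_width` seconds (50 ms by
#' default), truncated at four standard deviations and renormalized.
#' Reflection padding is used at trial boundaries so constant signals pass
#' through unchanged; smoothing is applied across the whole trial, before
#' any phase slicing.
#'
#' @param rates An unsmoothed `rate_tensor`.
#' @param kernel_width Kernel standard deviation in seconds.
#' @return A smoothed `rate_tensor`.
#' @export
smooth_rates <- function(rates, kernel_width = 0.05) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (isTRUE(rates$smoothed))
    stop("smooth_rates: input is already smoothed")
  if (!is.numeric(kernel_width) || kernel_width <= 0)
    stop("smooth_rates: kernel_width must be positive")
  d <- dim(rates$values)
  bw <- rates$bin_edges[2] - rates$bin_edges[1]
  S <- gaussian_smoother(d[3], kernel_width / bw)
  flat <- matrix(rates$values, nrow = d[1] * d[2], ncol = d[3])
  sm <- flat %*% t(S)
  out <- rates
  out$values <- array(sm, dim = d, dimnames = dimnames(rates$values))
  out$smoothed <- TRUE
  out$kernel_width <- kernel_width
  out
}

#' Re-align cue-phase bins to audio onset
#'
#' On auditory-cue trials the word audio starts 200-650 ms into the cue
#' phase; for time-resolved analyses of the cue response, cue-phase bins
#' are re-indexed so that the first retained cue bin starts at audio onset
#' (rounded to the nearest bin edge). Written-cue trials pass through with
#' no shift. Because shifts differ across trials, the trailing
#' `max(shift)` cue bins fall outside common coverage and are trimmed from
#' every trial, keeping the tensor rectangular.
#'
#' @param rates A `rate_tensor` aligned to trial start.
#' @param trials The matching [trial_table()].
#' @return A `rate_tensor` with `alignment = "audio_onset"`, fewer cue
#'   bins, and `phase_bins` updated.
#' @export
align_to_audio_onset <- function(rates, trials) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (!identical(rates$alignment, "trial_start"))
    stop("align_to_audio_onset: input must be aligned to trial_start")
  if (!"cue" %in% names(rates$phase_bins))
    stop("align_to_audio_onset: no cue phase in tensor")
  bw <- rates$bin_edges[2] - rates$bin_edges[1]
  aud <- trials$cue_modality == "auditory"
  if (any(aud & !is.finite(trials$audio_onset)))
    stop("align_to_audio_onset: auditory trial without audio_onset")
  shift <- ifelse(aud, round(trials$audio_onset / bw), 0L)
  cue_bins <- rates$phase_bins$cue
  s_max <- max(shift)
  if (s_max >= length(cue_bins))
    stop("align_to_audio_onset: shift exceeds cue-phase length")
  n_keep <- length(cue_bins) - s_max
  keep_rel <- seq_len(n_keep)
  d <- dim(rates$values)
  later <- setdiff(seq_len(d[3]), cue_bins)
  pre <- later[later < min(cue_bins)]
  post <- later[later > max(cue_bins)]
  new_nbins <- length(pre) + n_keep + length(post)
  vals <- array(0, dim = c(d[1], d[2], new_nbins))
  if (!is.null(dimnames(rates$values)))
    dimnames(vals) <- c(dimnames(rates$values)[1:2], list(NULL))
  for (t in seq_len(d[1])) {
    cue_sel <- cue_bins[keep_rel + shift[t]]
    vals[t, , ] <- rates$values[t, , c(pre, cue_sel, post)]
  }
  pb <- rates$phase_bins
  new_cue <- length(pre) + seq_len(n_keep)
  offset <- s_max
  pb <- lapply(names(pb), function(p) {
    b <- pb[[p]]
    if (identical(p, "cue")) return(new_cue)
    if (length(b) && min(b) > max(cue_bins)) return(b - offset)
    b
  })
  names(pb) <- names(rates$phase_bins)
  out <- rates
  out$values <- vals
  out$bin_edges <- rates$bin_edges[seq_len(new_nbins + 1L)]
  out$phase_bins <- pb
  out$alignment <- "audio_onset"
  out
}

#' Average rates within each task phase
#'
#' Collapses the time axis of a rate tensor to one mean rate per trial,
#' unit and phase — the feature representation used for phase-wise
#' decoding and per-phase tuning.
#'
#' @param rates A `rate_tensor` (smoothed or not).
#' @param trials The matching [trial_table()] (labels are carried along).
#' @return Object of class `phase_rates`: list with `phases` (named list
#'   of trials x units matrices, spikes/s) and `labels` (data.frame
#'   `trial_id`, `word`, `cue_modality`, `session_id`).
#' @export
phase_average <- function(rates, trials) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (!identical(as.integer(trials$trial_id), as.integer(rates$trial_ids)))
    stop("phase_average: trial tables do not match")
  mats <- lapply(names(rates$phase_bins), function(p) {
    b <- rates$phase_bins[[p]]
    if (!length(b)) stop("phase_average: phase ", p, " has zero bins")
    m <- rowMeans(rates$values[, , b, drop = FALSE], dims = 2)
    dimnames(m) <- list(as.character(rates$trial_ids), rates$unit_ids)
    m
  })
  names(mats) <- names(rates$phase_bins)
  structure(list(phases = mats,
                 labels = data.frame(trial_id = trials$trial_id,
                                     word = trials$word,
                                     cue_modality = trials$cue_modality,
                                     session_id = trials$session_id,
                                     stringsAsFactors = FALSE)),
            class = "phase_rates")
}

#' Export phase-averaged rates to tidy CSV
#'
#' @param pr A [phase_average()] result.
#' @param path Output CSV path; columns `trial_id`, `unit_id`, `phase`,
#'   `rate`.
#' @return `path`, invisibly.
#' @export
write_phase_rates_csv <- function(pr, path) {
  stopifnot(inherits(pr, "phase_rates"))
  rows <- do.call(rbind, lapply(names(pr$phases), function(p) {
    m <- pr$phases[[p]]
    data.frame(trial_id = rep(pr$labels$trial_id, ncol(m)),
               unit_id = rep(colnames(m), each = nrow(m)),
               phase = p, rate = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
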