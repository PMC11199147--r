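#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), as used throughout
#' the tuning and decoding significance analyses.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("adjust_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Indicator regression for the disjoint-cell design: response rows carry
# one word indicator each, reference rows (the same trials' ITI rates)
# carry none, so beta_0 is the ITI mean and beta_w = mean(FR | word w) -
# beta_0, exactly the least-squares solution of the augmented design.
# The residual variance of the word cells is pooled across words within
# the phase (as in the single regression model, giving it W*(n-1) df);
# the ITI reference keeps its own variance, and the two are combined in
# Welch form with Welch-Satterthwaite degrees of freedom, because phase
# windows of different durations yield rate estimates of different
# sampling variance and a fully pooled residual variance would
# mis-calibrate the test in the short delay phases.
word_regression_one <- function(resp, word, ref, words) {
  n0 <- length(ref)
  f <- factor(word, levels = words)
  nw <- as.numeric(table(f))
  if (any(nw < 2))
    stop("fit_word_regression: fewer than 2 trials for word(s): ",
         paste(words[nw < 2], collapse = ", "))
  b0 <- mean(ref)
  v0 <- stats::var(ref)
  mw <- as.numeric(tapply(resp, f, mean))
  vw <- as.numeric(tapply(resp, f, stats::var))
  beta <- mw - b0
  df_p <- sum(nw - 1)
  vp <- sum((nw - 1) * vw) / df_p        # pooled within-phase variance
  se2 <- vp / nw + v0 / n0
  se <- sqrt(se2)
  df <- se2^2 / ((vp / nw)^2 / df_p + (v0 / n0)^2 / (n0 - 1))
  degenerate <- se2 <= 1e-12
  tt <- ifelse(degenerate, 0, beta / se)
  p <- ifelse(degenerate | !is.finite(df), 1,
              2 * stats::pt(-abs(tt), pmax(df, 1)))
  data.frame(word = words, beta = beta, se = se, t = tt, p = p,
             stringsAsFactors = FALSE)
}

#' Word-tuning regression against the ITI baseline
#'
#' For every unit, fits the indicator regression
#' `FR = sum_w beta_w X_w + beta_0`, where `beta_0` is anchored to the
#' unit's average ITI firing rate by augmenting each fit with the same
#' trials' ITI rates as reference observations (all indicators 0). With
#' balanced data this makes `beta_w` the firing-rate change from baseline
#' for word `w`. A t-statistic is each coefficient divided by its standard
#' error, where the word cells' residual variance is pooled within the
#' phase and combined with the ITI reference variance in Welch
#' (unequal-variance) form with Welch-Satterthwaite degrees of freedom,
#' since phase windows of different durations yield rate estimates of
#' different sampling variance; two-sided p-values are
#' FDR-adjusted (Benjamini-Hochberg) within
#' each unit's `W` word coefficients, and a unit is tuned (in a bin or
#' phase) if at least one adjusted p-value is below `alpha`. The fit runs
#' either per 50-ms time bin (tuning timecourses) or on phase-averaged
#' rates (phase comparisons).
#'
#' @param rates A `rate_tensor` (typically smoothed).
#' @param trials The matching [trial_table()].
#' @param granularity `"per_phase"` or `"per_bin"`.
#' @param alpha Tuned-flag threshold on the adjusted p-value.
#' @param words The word vocabulary the fit must cover (defaults to the
#'   words present in `trials`); a word with fewer than two trials — for
#'   example after error-trial exclusion emptied it — raises an error
#'   naming the word.
#' @return Object of class `tuning_result`: `table` (long data.frame:
#'   `unit_id`, `where` (phase name or bin index), `word`, `beta`, `se`,
#'   `t`, `p`, `p_adj`, `tuned_word`), `tuned` (units x where logical
#'   matrix), `granularity`, `words`, `alpha`.
#' @export
fit_word_regression <- function(rates, trials,
                                granularity = c("per_phase", "per_bin"),
                                alpha = 0.05,
                                words = sort(unique(trials$word))) {
  granularity <- match.arg(granularity)
  stopifnot(inherits(rates, "rate_tensor"))
  if (!identical(as.integer(trials$trial_id), as.integer(rates$trial_ids)))
    stop("fit_word_regression: trial tables do not match")
  missing_w <- setdiff(words, trials$word)
  if (length(missing_w))
    stop("fit_word_regression: no trials for word(s): ",
         paste(missing_w, collapse = ", "))
  iti_bins <- rates$phase_bins$ITI
  if (is.null(iti_bins) || !length(iti_bins))
    stop("fit_word_regression: no ITI bins available for baseline")
  ref_all <- rowMeans(rates$values[, , iti_bins, drop = FALSE], dims = 2)
  unit_ids <- rates$unit_ids
  if (granularity == "per_phase") {
    slices <- lapply(rates$phase_bins, function(b)
      rowMeans(rates$values[, , b, drop = FALSE], dims = 2))
    where_lab <- names(rates$phase_bins)
  } else {
    n_bins <- dim(rates$values)[3]
    slices <- lapply(seq_len(n_bins), function(b) rates$values[, , b])
    where_lab <- as.character(seq_len(n_bins))
  }
  rows <- vector("list", length(slices) * length(unit_ids))
  tuned <- matrix(FALSE, length(unit_ids), length(slices),
                  dimnames = list(unit_ids, where_lab))
  k <- 0L
  for (s in seq_along(slices)) {
    m <- slices[[s]]
    for (u in seq_along(unit_ids)) {
      fit <- word_regression_one(m[, u], trials$word, ref_all[, u], words)
      fit$p_adj <- adjust_fdr(fit$p)
      fit$tuned_word <- fit$p_adj < alpha
      fit <- cbind(unit_id = unit_ids[u], where = where_lab[s], fit,
                   stringsAsFactors = FALSE)
      tuned[u, s] <- any(fit$tuned_word)
      k <- k + 1L
      rows[[k]] <- fit
    }
  }
  structure(list(table = do.call(rbind, rows), tuned = tuned,
                 granularity = granularity, words = words, alpha = alpha),
            class = "tuning_result")
}

#' Kruskal-Wallis word tuning per phase
#'
#' Non-parametric alternative tuning definition: per unit and task phase,
#' tests whether phase-averaged firing rates differ between words
#' (Kruskal-Wallis H with tie correction, chi-square approximation).
#' P-values are FDR-adjusted across units within each phase; a unit is
#' tuned in a phase if its adjusted p-value is below `alpha`. Units with
#' identical rates on every trial are reported untuned with p = 1.
#'
#' @param pr A [phase_average()] result.
#' @param alpha Tuned-flag threshold.
#' @return Object of class `tuning_result` with `table` (`unit_id`,
#'   `where`, `H`, `p`, `p_adj`, `df`), `tuned` matrix, `granularity =
#'   "per_phase"`.
#' @export
kruskal_wallis_tuning <- function(pr, alpha = 0.05) {
  stopifnot(inherits(pr, "phase_rates"))
  g <- factor(pr$labels$word)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("kruskal_wallis_tuning: need >= 2 words with >= 2 trials each")
  phases <- names(pr$phases)
  unit_ids <- colnames(pr$phases[[1]])
  rows <- list()
  tuned <- matrix(FALSE, length(unit_ids), length(phases),
                  dimnames = list(unit_ids, phases))
  for (ph in phases) {
    m <- pr$phases[[ph]]
    H <- p <- numeric(length(unit_ids))
    for (u in seq_along(unit_ids)) {
      x <- m[, u]
      if (stats::var(x) <= 1e-24) {
        H[u] <- 0; p[u] <- 1
      } else {
        kt <- stats::kruskal.test(x, g)
        H[u] <- unname(kt$statistic); p[u] <- kt$p.value
      }
    }
    p_adj <- adjust_fdr(p)
    tuned[, ph] <- p_adj < alpha
    rows[[ph]] <- data.frame(unit_id = unit_ids, where = ph, H = H,
                             df = nlevels(g) - 1L, p = p, p_adj = p_adj,
                             stringsAsFactors = FALSE)
  }
  structure(list(table = do.call(rbind, rows), tuned = tuned,
                 granularity = "per_phase", words = levels(g),
                 alpha = alpha),
            class = "tuning_result")
}

#' Fraction of tuned units across sessions, with confidence interval
#'
#' Averages the percentage of tuned units per bin (or phase) over
#' sessions and attaches the 95% Student-t confidence interval of the
#' mean, `mean +/- t_{0.975, n-1} * SE`.
#'
#' @param results List of per-session `tuning_result` objects with equal
#'   granularity and matching bins/phases.
#' @param conf Confidence level (default 0.95).
#' @return Data.frame: `where`, `mean_pct`, `ci_lo`, `ci_hi`,
#'   `n_sessions`. With a single session the CI is `NA` (undefined).
#' @export
tuned_fraction_summary <- function(results, conf = 0.95) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "tuning_result")))
  fr <- vapply(results, function(r) 100 * colMeans(r$tuned),
               numeric(ncol(results[[1]]$tuned)))
  fr <- matrix(fr, ncol = length(results))  # where x sessions
  n <- length(results)
  mean_pct <- rowMeans(fr)
  if (n >= 2) {
    se <- apply(fr, 1, stats::sd) / sqrt(n)
    tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
    lo <- mean_pct - tcrit * se
    hi <- mean_pct + tcrit * se
  } else {
    lo <- hi <- rep(NA_real_, length(mean_pct))
  }
  data.frame(where = colnames(results[[1]]$tuned), mean_pct = mean_pct,
             ci_lo = lo, ci_hi = hi, n_sessions = n,
             stringsAsFactors = FALSE)
}

#' Paired comparison of tuned fractions between phases
#'
#' Tests, across sessions, whether tuning during each action phase (cue,
#' internal, speech) exceeds tuning in the preceding rest phase (ITI, D1,
#' D2): paired two-tailed t-test per pair, Cohen's d for paired samples
#' (mean difference / SD of differences), Benjamini-Hochberg correction
#' across the tested pairs.
#'
#' @param fractions Sessions x phases numeric matrix of tuned percentages
#'   (column names are phase names), e.g. built from per-session
#'   `tuning_result$tuned` column means.
#' @param pairs List of length-2 character vectors `(rest, action)`;
#'   defaults to `(ITI, cue)`, `(D1, internal)`, `(D2, speech)`.
#' @return Data.frame: `rest`, `action`, `t`, `df`, `p`, `p_adj`,
#'   `cohens_d`.
#' @export
compare_phase_tuning <- function(fractions,
                                 pairs = list(c("ITI", "cue"),
                                              c("D1", "internal"),
                                              c("D2", "speech"))) {
  fractions <- as.matrix(fractions)
  out <- lapply(pairs, function(pr) {
    if (!all(pr %in% colnames(fractions)))
      stop("compare_phase_tuning: unknown phase in pair ",
           paste(pr, collapse = "/"))
    d <- fractions[, pr[2]] - fractions[, pr[1]]
    n <- length(d)
    if (stats::sd(d) == 0) {
      tt <- 0; p <- 1; cd <- 0
    } else {
      ht <- stats::t.test(fractions[, pr[2]], fractions[, pr[1]],
                          paired = TRUE)
      tt <- unname(ht$statistic); p <- ht$p.value
      cd <- mean(d) / stats::sd(d)
    }
    data.frame(rest = pr[1], action = pr[2], t = tt, df = n - 1L, p = p,
               cohens_d = cd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adj <- adjust_fdr(out$p)
  out[, c("rest", "action", "t", "df", "p", "p_adj", "cohens_d")]
}

# Per-unit sets of tuned words in one phase of a per_phase regression
# tuning_result.
tuned_word_sets <- function(result, phase) {
  stopifnot(inherits(result, "tuning_result"))
  if (!"tuned_word" %in% names(result$table))
    stop("tuning_overlap: needs a regression tuning_result with per-word flags")
  tb <- result$table[result$table$where == phase, ]
  if (!nrow(tb)) stop("tuning_overlap: phase not found: ", phase)
  lapply(split(tb, tb$unit_id), function(d) d$word[d$tuned_word])
}

#' Overlap of tuned populations between two analyses
#'
#' Given per-word tuning in a reference analysis A (for example the
#' internal-speech phase) and a comparison analysis B (for example
#' vocalized speech), computes (i) the percentage of units tuned in A
#' that are also tuned in B, and (ii) the percentage of units tuned in A
#' that share at least one identical tuned word in B (preserved tuning).
#'
#' @param result_a,result_b Per-phase regression `tuning_result` objects
#'   over the same unit roster.
#' @param phase_a,phase_b Phase to read from each result.
#' @return List: `n_tuned_a`, `pct_also_tuned`, `pct_preserved` (both
#'   `NA` when no unit is tuned in A, with `defined = FALSE`).
#' @export
tuning_overlap <- function(result_a, result_b, phase_a, phase_b) {
  sa <- tuned_word_sets(result_a, phase_a)
  sb <- tuned_word_sets(result_b, phase_b)
  if (!setequal(names(sa), names(sb)))
    stop("tuning_overlap: unit rosters differ")
  sb <- sb[names(sa)]
  tuned_a <- names(sa)[lengths(sa) > 0]
  if (!length(tuned_a))
    return(list(n_tuned_a = 0L, pct_also_tuned = NA_real_,
                pct_preserved = NA_real_, defined = FALSE))
  also <- vapply(tuned_a, function(u) length(sb[[u]]) > 0, TRUE)
  pres <- vapply(tuned_a, function(u)
    length(intersect(sa[[u]], sb[[u]])) > 0, TRUE)
  list(n_tuned_a = length(tuned_a),
       pct_also_tuned = 100 * mean(also),
       pct_preserved = 100 * mean(pres),
       defined = TRUE)
}

#' Export a tuning result to tidy CSV
#' @param result A `tuning_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tuning_csv <- function(result, path) {
  stopifnot(inherits(result, "tuning_result"))
  utils::write.csv(result$table, path, row.names = FALSE)
  invisible(path)
}
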