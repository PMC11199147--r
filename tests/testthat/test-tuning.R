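# Minimal tuning_result stub for the overlap statistics.
stub_tuning <- function(sets, phase, words) {
  tb <- do.call(rbind, lapply(names(sets), function(u) {
    data.frame(unit_id = u, where = phase, word = words,
               tuned_word = words %in% sets[[u]],
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tb, granularity = "per_phase", words = words,
                 alpha = 0.05),
            class = "tuning_result")
}

test_that("word regression equals the normal-equations oracle", {
  cfg <- small_config()
  words <- cfg$words
  n_rep <- 4
  tr <- manual_trials(cfg, rep(words, n_rep))
  n_bins <- round(trial_duration(cfg) / cfg$bin_width)
  set.seed(31)
  vals <- array(stats::rnorm(length(words) * n_rep * 2 * n_bins, 10, 2),
                c(length(words) * n_rep, 2, n_bins))
  rt <- manual_tensor(vals, cfg)
  res <- fit_word_regression(rt, tr, "per_phase")
  pb <- phase_bins(cfg)
  for (u in 1:2) {
    iti <- rowMeans(sapply(pb$ITI, function(b) vals[, u, b]))
    for (ph in c("internal", "speech")) {
      y_resp <- rowMeans(sapply(pb[[ph]], function(b) vals[, u, b]))
      ws <- sort(unique(tr$word))
      # normal-equations oracle on the augmented design
      X <- rbind(cbind(1, outer(tr$word, ws, `==`) + 0),
                 cbind(1, matrix(0, nrow(tr), length(ws))))
      y <- c(y_resp, iti)
      beta_hat <- solve(t(X) %*% X, t(X) %*% y)
      got <- res$table[res$table$unit_id == rt$unit_ids[u] &
                         res$table$where == ph, ]
      got <- got[match(ws, got$word), ]
      expect_lt(max(abs(got$beta - beta_hat[-1])), 1e-10)
      # beta_w is the class mean minus the ITI mean; t and p follow the
      # pooled-within-phase Welch form, recomputed here with plain sums
      vp_num <- 0; df_p <- 0
      for (w in ws) {
        yw <- y_resp[tr$word == w]
        vp_num <- vp_num + sum((yw - mean(yw))^2)
        df_p <- df_p + length(yw) - 1
      }
      vp <- vp_num / df_p
      v0 <- sum((iti - mean(iti))^2) / (length(iti) - 1)
      for (w in ws) {
        yw <- y_resp[tr$word == w]
        expect_equal(got$beta[got$word == w], mean(yw) - mean(iti),
                     tolerance = 1e-10)
        se2 <- vp / length(yw) + v0 / length(iti)
        dfw <- se2^2 / ((vp / length(yw))^2 / df_p +
                          (v0 / length(iti))^2 / (length(iti) - 1))
        t_or <- (mean(yw) - mean(iti)) / sqrt(se2)
        expect_equal(got$t[got$word == w], t_or, tolerance = 1e-10)
        expect_equal(got$p[got$word == w],
                     2 * stats::pt(-abs(t_or), dfw), tolerance = 1e-10)
      }
    }
  }
  # tuned flag tracks min adjusted p < 0.05
  per_unit <- split(res$table, list(res$table$unit_id, res$table$where))
  for (d in per_unit)
    expect_equal(unname(res$tuned[d$unit_id[1], d$where[1]]),
                 min(d$p_adj) < 0.05)
})

test_that("constant rates yield zero coefficients and no tuning", {
  cfg <- small_config()
  tr <- manual_trials(cfg, rep(cfg$words, 3))
  n_bins <- round(trial_duration(cfg) / cfg$bin_width)
  rt <- manual_tensor(array(5, c(nrow(tr), 2, n_bins)), cfg)
  res <- fit_word_regression(rt, tr, "per_phase")
  expect_true(all(res$table$beta == 0))
  expect_true(all(res$table$p == 1))
  expect_false(any(res$tuned))
})

test_that("per-bin and per-phase regressions agree in sign for real effects", {
  cfg <- task_config()
  ss <- quick_session(n_units = 5, n_reps = 12, seed = 41, config = cfg,
                      tuned_fraction = c(internal = 1), word_prob = 1,
                      effect_mean = 8, effect_sd = 1)
  sr <- session_rates(ss)
  per_ph <- fit_word_regression(sr$rates, ss$trials, "per_phase")
  per_bin <- fit_word_regression(sr$rates, ss$trials, "per_bin")
  pb <- phase_bins(cfg)$internal
  mid <- as.character(pb[ceiling(length(pb) / 2)])
  for (u in sr$rates$unit_ids) {
    a <- per_ph$table[per_ph$table$unit_id == u &
                        per_ph$table$where == "internal", ]
    b <- per_bin$table[per_bin$table$unit_id == u &
                         per_bin$table$where == mid, ]
    strong <- a$word[abs(a$t) > 4]
    for (w in strong)
      expect_equal(sign(b$beta[b$word == w]), sign(a$beta[a$word == w]))
  }
})

test_that("FDR adjustment is Benjamini-Hochberg step-up", {
  expect_equal(adjust_fdr(0.03), 0.03)
  p <- c(0.01, 0.02, 0.03, 0.04)
  # brute-force min_{j >= i} m * p_(j) / j
  m <- length(p)
  ord <- order(p)
  brute <- numeric(m)
  for (i in seq_len(m))
    brute[ord[i]] <- min(1, min(m * p[ord[i:m]] / (i:m) *
                                  (i:m) / (i:m)))  # p sorted already
  brute2 <- sapply(seq_len(m), function(i)
    min(sapply(i:m, function(j) m * sort(p)[j] / j)))
  expect_equal(adjust_fdr(p), rep(0.04, 4))
  expect_equal(sort(adjust_fdr(p)), pmin(1, brute2))
  expect_equal(adjust_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(adjust_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # monotone non-decreasing in sorted-p order
  set.seed(5)
  pr <- stats::runif(50)
  expect_true(all(diff(adjust_fdr(pr)[order(pr)]) >= -1e-15))
})

test_that("Kruskal-Wallis tuning matches the rank-sum formula", {
  cfg <- small_config(words = c("python", "spoon", "cowboy"))
  tr <- manual_trials(cfg, rep(cfg$words, each = 3))
  n_bins <- round(trial_duration(cfg) / cfg$bin_width)
  vals <- array(1, c(9, 1, n_bins))
  x <- c(2.1, 3.4, 1.2, 7.7, 8.1, 6.9, 4.4, 5.0, 3.9)   # no ties
  for (t in 1:9) vals[t, 1, phase_bins(cfg)$internal] <- x[t]
  pr <- phase_average(manual_tensor(vals, cfg), tr)
  res <- kruskal_wallis_tuning(pr)
  # textbook H from explicit ranks
  r <- rank(x)
  g <- rep(1:3, each = 3)
  H <- 12 / (9 * 10) * sum(tapply(r, g, sum)^2 / 3) - 3 * 10
  got <- res$table[res$table$where == "internal", ]
  expect_equal(got$H, H, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_equal(got$p, stats::pchisq(H, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # constant unit: untuned with p = 1
  got_iti <- res$table[res$table$where == "ITI", ]
  expect_equal(got_iti$p, 1)
  expect_false(res$tuned[1, "ITI"])
})

test_that("Kruskal-Wallis rejection rate under the null is near alpha", {
  cfg <- small_config()
  tr <- manual_trials(cfg, rep(cfg$words, 6))
  n_bins <- round(trial_duration(cfg) / cfg$bin_width)
  set.seed(71)
  n_sim <- 400
  rej <- 0
  for (s in seq_len(n_sim)) {
    x <- stats::rnorm(nrow(tr))
    p <- stats::kruskal.test(x, factor(tr$word))$p.value
    rej <- rej + (p < 0.05)
  }
  # raw (pre-FDR) rejection rate approximately alpha
  expect_lt(abs(rej / n_sim - 0.05), 3 * sqrt(0.05 * 0.95 / n_sim))
})

test_that("session summaries use the Student-t confidence multiplier", {
  cfg <- small_config()
  mk <- function(fracs) {
    tuned <- matrix(FALSE, 10, 2, dimnames = list(paste0("u", 1:10),
                                                  c("ITI", "internal")))
    tuned[seq_len(fracs[1]), 1] <- TRUE
    tuned[seq_len(fracs[2]), 2] <- TRUE
    structure(list(table = NULL, tuned = tuned, granularity = "per_phase",
                   words = cfg$words, alpha = 0.05),
              class = "tuning_result")
  }
  # identical sessions: zero-width interval
  same <- tuned_fraction_summary(list(mk(c(2, 5)), mk(c(2, 5))))
  expect_equal(same$ci_lo, same$ci_hi)
  expect_equal(same$mean_pct, c(20, 50))
  # ten sessions: multiplier is the 97.5th Student-t percentile, 9 d.f.
  fracs <- cbind(ITI = 1:10, internal = rep(5, 10))
  results <- lapply(seq_len(10), function(s) mk(fracs[s, ]))
  out <- tuned_fraction_summary(results)
  se <- stats::sd(10 * (1:10)) / sqrt(10)
  expect_equal(out$ci_hi[1] - out$mean_pct[1], 2.262157 * se,
               tolerance = 1e-6)
  # single session: interval undefined
  one <- tuned_fraction_summary(list(mk(c(2, 5))))
  expect_true(all(is.na(one$ci_lo)))
})

test_that("phase-pair comparisons report paired t and Cohen's d", {
  frac <- cbind(ITI = c(10, 12, 9, 11), cue = c(30, 35, 28, 33),
                D1 = c(10, 12, 9, 11), internal = c(25, 30, 22, 28),
                D2 = c(10, 12, 9, 11), speech = c(40, 45, 38, 44))
  out <- compare_phase_tuning(frac)
  expect_equal(out$rest, c("ITI", "D1", "D2"))
  expect_equal(out$action, c("cue", "internal", "speech"))
  d <- frac[, "cue"] - frac[, "ITI"]
  expect_equal(out$t[1], mean(d) / (stats::sd(d) / sqrt(4)),
               tolerance = 1e-12)
  expect_equal(out$cohens_d[1], mean(d) / stats::sd(d), tolerance = 1e-12)
  expect_equal(out$df, rep(3L, 3))
  # identical phases: t = 0, p = 1, d = 0
  same <- compare_phase_tuning(cbind(ITI = c(1, 2, 3), cue = c(1, 2, 3),
                                     D1 = c(1, 2, 3), internal = c(1, 2, 3),
                                     D2 = c(1, 2, 3), speech = c(1, 2, 3)))
  expect_equal(same$t, rep(0, 3))
  expect_equal(same$p, rep(1, 3))
  expect_equal(same$cohens_d, rep(0, 3))
})

test_that("tuning overlap statistics follow set logic", {
  words <- c("python", "spoon", "cowboy", "bindip")
  a <- stub_tuning(list(u1 = "python", u2 = "cowboy", u3 = character(0)),
                   "internal", words)
  b <- stub_tuning(list(u1 = c("python", "spoon"), u2 = "spoon",
                        u3 = "python"), "speech", words)
  ov <- tuning_overlap(a, b, "internal", "speech")
  expect_equal(ov$n_tuned_a, 2L)
  # u1 and u2 both tuned in B -> 100%; only u1 shares a word -> 50%
  expect_equal(ov$pct_also_tuned, 100)
  expect_equal(ov$pct_preserved, 50)

  ident <- tuning_overlap(a, a, "internal", "internal")
  expect_equal(ident$pct_also_tuned, 100)
  expect_equal(ident$pct_preserved, 100)

  disj <- stub_tuning(list(u1 = character(0), u2 = character(0),
                           u3 = "python"), "speech", words)
  ov2 <- tuning_overlap(a, disj, "internal", "speech")
  expect_equal(ov2$pct_also_tuned, 0)
  expect_equal(ov2$pct_preserved, 0)

  none <- stub_tuning(list(u1 = character(0), u2 = character(0),
                           u3 = character(0)), "internal", words)
  und <- tuning_overlap(none, b, "internal", "speech")
  expect_false(und$defined)
  expect_true(is.na(und$pct_also_tuned))
})
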