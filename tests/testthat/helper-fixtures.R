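# Shared fixtures: small synthetic sessions and hand-rolled oracles used
# across the test files. Everything is generated in code at test time.

# A small task configuration with a reduced vocabulary, full phase set.
small_config <- function(words = c("python", "spoon", "cowboy", "bindip")) {
  task_config(words = words)
}

# Quick synthetic session: returns trials, spikes, truth, config.
quick_session <- function(n_units = 8, n_reps = 3, seed = 11,
                          config = small_config(),
                          modalities = "written",
                          tuned_fraction = c(internal = 0.5, speech = 0.5),
                          area = "SMG", ...) {
  pop <- sample_population(
    population_spec(n_units = n_units, area = area,
                    tuned_fraction = tuned_fraction, ...),
    config, seed = seed)
  sim <- simulate_session(pop, config, n_reps = n_reps,
                          cue_modalities = modalities, seed = seed + 1)
  c(sim, list(config = config))
}

# Session -> smoothed rate tensor and phase rates.
session_rates <- function(ss) {
  rt <- smooth_rates(bin_spike_counts(ss$spikes, ss$trials, ss$config),
                     ss$config$kernel_width)
  list(rates = rt, pr = phase_average(rt, ss$trials))
}

# Build a trial_table directly (no simulation), one modality, balanced.
manual_trials <- function(config, words_per_trial, modality = "written",
                          audio_onset = NA_real_) {
  on <- phase_onsets(config)
  n <- length(words_per_trial)
  df <- data.frame(trial_id = seq_len(n), session_id = "manual",
                   word = words_per_trial, cue_modality = modality,
                   stringsAsFactors = FALSE)
  for (p in config$phase_names) df[[paste0("onset_", p)]] <- on[[p]]
  df$audio_onset <- audio_onset
  df$error_kind <- "none"
  trial_table(df, config)
}

# Wrap a trials x units x bins array as a rate_tensor.
manual_tensor <- function(values, config) {
  structure(list(values = values,
                 bin_edges = seq(0, by = config$bin_width,
                                 length.out = dim(values)[3] + 1L),
                 phase_bins = phase_bins(config),
                 alignment = "trial_start", smoothed = FALSE,
                 kernel_width = NA_real_,
                 trial_ids = seq_len(dim(values)[1]),
                 unit_ids = dimnames(values)[[2]] %||%
                   paste0("u", seq_len(dim(values)[2]))),
            class = "rate_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force LDA oracle: explicit class means, pooled covariance and
# discriminant loop; PCA by eigendecomposition of the covariance matrix,
# keeping the smallest count of leading axes whose cumulative variance
# share strictly exceeds the threshold.
oracle_pca_lda_predict <- function(xtr, ytr, xte, classes,
                                   var_threshold = 0.95) {
  ctr <- colMeans(xtr)
  xc <- sweep(xtr, 2, ctr)
  eg <- eigen(crossprod(xc), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  keep <- ev > max(ev) * 1e-12
  share <- cumsum(ev[keep]) / sum(ev[keep])
  q <- if (var_threshold >= 1) sum(keep) else which(share > var_threshold)[1]
  V <- eg$vectors[, seq_len(q), drop = FALSE]
  ztr <- xc %*% V
  zte <- sweep(matrix(xte, ncol = ncol(xtr)), 2, ctr) %*% V
  K <- length(classes)
  mus <- matrix(0, K, q)
  S <- matrix(0, q, q)
  for (k in seq_len(K)) {
    rows <- ztr[ytr == classes[k], , drop = FALSE]
    mus[k, ] <- colMeans(rows)
    S <- S + crossprod(sweep(rows, 2, mus[k, ]))
  }
  S <- S / (nrow(ztr) - K)
  Sinv <- solve(S)
  pred <- character(nrow(zte))
  for (i in seq_len(nrow(zte))) {
    d <- numeric(K)
    for (k in seq_len(K))
      d[k] <- zte[i, ] %*% Sinv %*% mus[k, ] -
        0.5 * mus[k, ] %*% Sinv %*% mus[k, ]
    pred[i] <- classes[which.max(d)]
  }
  pred
}

# Nested-loop marginalization oracle on a 5-d array X[n,t,c,w,k]:
# classical factorial-ANOVA effects computed with explicit loops.
oracle_marginalize <- function(X) {
  dn <- dim(X)
  A <- array(0, dn[1:4])
  for (n in 1:dn[1]) for (t in 1:dn[2]) for (c in 1:dn[3])
    for (w in 1:dn[4]) A[n, t, c, w] <- mean(X[n, t, c, w, ])
  grand <- numeric(dn[1])
  for (n in 1:dn[1]) grand[n] <- mean(A[n, , , ])
  eff <- function(fun) {
    out <- array(0, dn[1:4])
    for (n in 1:dn[1]) for (t in 1:dn[2]) for (c in 1:dn[3])
      for (w in 1:dn[4]) out[n, t, c, w] <- fun(n, t, c, w)
    out
  }
  m_t <- eff(function(n, t, c, w) mean(A[n, t, , ]) - grand[n])
  m_c <- eff(function(n, t, c, w) mean(A[n, , c, ]) - grand[n])
  m_w <- eff(function(n, t, c, w) mean(A[n, , , w]) - grand[n])
  m_tc <- eff(function(n, t, c, w)
    mean(A[n, t, c, ]) - grand[n] - m_t[n, t, 1, 1] - m_c[n, 1, c, 1])
  m_tw <- eff(function(n, t, c, w)
    mean(A[n, t, , w]) - grand[n] - m_t[n, t, 1, 1] - m_w[n, 1, 1, w])
  m_cw <- eff(function(n, t, c, w)
    mean(A[n, , c, w]) - grand[n] - m_c[n, 1, c, 1] - m_w[n, 1, 1, w])
  m_tcw <- eff(function(n, t, c, w)
    A[n, t, c, w] - grand[n] - m_t[n, t, 1, 1] - m_c[n, 1, c, 1] -
      m_w[n, 1, 1, w] - m_tc[n, t, c, 1] - m_tw[n, t, 1, w] -
      m_cw[n, 1, c, w])
  noise <- X - array(A, dn)
  list(grand = grand, timing = m_t, cue = m_c + m_tc, word = m_w + m_tw,
       cue_word = m_cw + m_tcw, noise = noise)
}

# Random balanced tensor with smooth structure plus noise.
random_tensor <- function(N = 4, T = 6, C = 2, W = 3, K = 3, seed = 1,
                          noise_sd = 1) {
  set.seed(seed)
  X <- array(stats::rnorm(N * T * C * W * K, sd = noise_sd),
             dim = c(N, T, C, W, K))
  for (n in 1:N) {
    X[n, , , , ] <- X[n, , , , ] + stats::rnorm(1, 5, 2) +
      rep(sin(seq_len(T) / 2) * stats::rnorm(1), times = C * W * K)
  }
  structure(list(values = X, modalities = paste0("c", 1:C),
                 words = paste0("w", 1:W), n_replaced = 0L),
            class = "trial_tensor")
}
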