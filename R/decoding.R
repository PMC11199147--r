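#' Train a PCA + shared-covariance LDA word decoder
#'
#' Features are principal components of the training rows only: data are
#' centered, and the smallest set of leading components whose cumulative
#' variance share strictly exceeds `var_threshold` (default 0.95) is
#' retained. In that feature space a linear discriminant model is fit with
#' one mean per word, a single pooled covariance matrix shared by all
#' words, and equal class priors. When the pooled covariance is
#' ill-conditioned (training rows per residual degree of freedom not
#' exceeding the feature count) it is shrunk toward a scaled identity with
#' the analytic Ledoit-Wolf intensity.
#'
#' @param x Training matrix, trials x units (phase-averaged rates).
#' @param labels Word label per row.
#' @param classes Class order (ties in the posterior are broken toward the
#'   earliest class in this order). Defaults to `sort(unique(labels))`.
#' @param var_threshold Cumulative PCA variance share to exceed; at 1 (or
#'   above) all components are kept.
#' @return Object of class `word_decoder`.
#' @export
train_decoder <- function(x, labels, classes = sort(unique(labels)),
                          var_threshold = 0.95) {
  x <- as.matrix(x)
  f <- factor(labels, levels = classes)
  if (anyNA(f)) stop("train_decoder: labels outside classes")
  cnt <- table(f)
  if (length(classes) < 2) stop("train_decoder: need >= 2 classes")
  if (any(cnt < 2))
    stop("train_decoder: class(es) with < 2 training trials: ",
         paste(classes[cnt < 2], collapse = ", "))
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  share <- cumsum(ev) / sum(ev)
  q <- if (var_threshold >= 1) length(ev) else
    which(share > var_threshold)[1]
  rot <- sv$v[, seq_len(q), drop = FALSE]
  z <- xc %*% rot
  K <- length(classes)
  n <- nrow(z)
  mu <- matrix(0, K, q)
  zc <- z
  for (k in seq_len(K)) {
    idx <- which(f == classes[k])
    mu[k, ] <- colMeans(z[idx, , drop = FALSE])
    zc[idx, ] <- sweep(z[idx, , drop = FALSE], 2, mu[k, ])
  }
  S <- crossprod(zc) / (n - K)
  if (n - K <= q) S <- lw_shrink(zc, S, n - K)
  Sinv <- tryCatch(solve(S), error = function(e) {
    solve(S + diag(1e-8 * mean(diag(S)) + 1e-12, q))
  })
  A <- Sinv %*% t(mu)                      # q x K
  const <- -0.5 * colSums(t(mu) * A)       # -(1/2) mu_k' Sinv mu_k
  structure(list(center = center, rotation = rot, q = q,
                 classes = classes, means = mu, cov = S,
                 A = A, const = const, var_threshold = var_threshold),
            class = "word_decoder")
}

# Ledoit-Wolf analytic shrinkage of a pooled covariance toward a scaled
# identity, from the within-class-centered rows zc; df = n - K.
lw_shrink <- function(zc, S, df) {
  q <- ncol(S)
  m <- sum(diag(S)) / q
  d2 <- sum((S - diag(m, q))^2)
  if (d2 <= 0) return(S + diag(1e-8 * max(m, 1e-12), q))
  n <- nrow(zc)
  b2 <- 0
  for (i in seq_len(n)) {
    zi <- zc[i, ]
    b2 <- b2 + sum((tcrossprod(zi) * (n / df) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  rho <- b2 / d2
  rho * diag(m, q) + (1 - rho) * S
}

#' Predict word labels with a trained decoder
#'
#' @param object A [train_decoder()] model.
#' @param newdata Matrix (or single row vector) of trials x units rates.
#' @param ... Unused.
#' @return Character vector of predicted word labels; posterior ties are
#'   broken toward the earliest class in the model's class order.
#' @export
predict.word_decoder <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  z <- sweep(as.matrix(newdata), 2, object$center) %*% object$rotation
  disc <- z %*% object$A + rep(object$const, each = nrow(z))
  object$classes[apply(disc, 1, which.max)]   # which.max: first = lowest index
}

#' Leave-one-out decoding of words from one task phase
#'
#' For each trial, the full pipeline (PCA projection and LDA) is refit on
#' the remaining trials and the held-out trial is classified, so no
#' information from the test trial reaches the model. Accuracy is the
#' percentage of correctly classified trials; the confusion matrix counts
#' true x predicted labels.
#'
#' @param pr A [phase_average()] result.
#' @param phase Phase name to decode from.
#' @param classes Class order (default: sorted words present).
#' @param var_threshold PCA cumulative-variance threshold.
#' @return Object of class `decoding_result`: `accuracy_pct`, `confusion`
#'   (true x predicted counts), `predicted`, `phase`, `n_trials`,
#'   `n_units`.
#' @export
loo_cv_decode <- function(pr, phase, classes = NULL, var_threshold = 0.95) {
  stopifnot(inherits(pr, "phase_rates"))
  x <- pr$phases[[phase]]
  if (is.null(x)) stop("loo_cv_decode: unknown phase ", phase)
  labels <- pr$labels$word
  if (is.null(classes)) classes <- sort(unique(labels))
  decode_loo_matrix(x, labels, classes, var_threshold, phase)
}

decode_loo_matrix <- function(x, labels, classes, var_threshold, phase) {
  n <- nrow(x)
  if (n < length(classes) + 1)
    stop("loo_cv_decode: need more trials than classes")
  pred <- character(n)
  for (i in seq_len(n)) {
    m <- train_decoder(x[-i, , drop = FALSE], labels[-i], classes,
                       var_threshold)
    pred[i] <- predict(m, x[i, ])
  }
  conf <- table(factor(labels, classes), factor(pred, classes))
  structure(list(accuracy_pct = 100 * mean(pred == labels),
                 confusion = unclass(conf), predicted = pred,
                 phase = phase, n_trials = n, n_units = ncol(x)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("LOO decoding [%s]: %.1f%% (%d trials, %d units)\n",
              x$phase, x$accuracy_pct, x$n_trials, x$n_units))
  invisible(x)
}

#' Shuffle-label significance of decoding accuracy
#'
#' Builds a null distribution by rerunning the full leave-one-out
#' classification `n_shuffles` times with word labels permuted within the
#' session (class counts preserved). The observed accuracy is graded
#' against the null percentiles: above the 99.5th percentile is reported
#' as `P < 0.01`, above the 97.5th as `P < 0.05`, otherwise not
#' significant.
#'
#' @param pr A [phase_average()] result.
#' @param phase Phase to decode.
#' @param n_shuffles Number of label permutations (100 for offline
#'   analyses; 1,000 for online-protocol grading).
#' @param seed Integer seed for the permutations.
#' @param classes,var_threshold Passed to the decoder.
#' @return List: `observed_pct`, `null_pct` (vector), `null_mean_pct`,
#'   `p975`, `p995`, `grade` (`"P<0.01"`, `"P<0.05"` or `"ns"`).
#' @export
shuffle_significance <- function(pr, phase, n_shuffles = 100, seed = 1L,
                                 classes = NULL, var_threshold = 0.95) {
  if (n_shuffles < 1) stop("shuffle_significance: n_shuffles must be >= 1")
  stopifnot(inherits(pr, "phase_rates"))
  x <- pr$phases[[phase]]
  labels <- pr$labels$word
  if (is.null(classes)) classes <- sort(unique(labels))
  obs <- decode_loo_matrix(x, labels, classes, var_threshold,
                           phase)$accuracy_pct
  rs <- local_rng(seed)
  null_acc <- vapply(seq_len(n_shuffles), function(s) {
    decode_loo_matrix(x, sample(labels), classes, var_threshold,
                      phase)$accuracy_pct
  }, 0)
  p975 <- stats::quantile(null_acc, 0.975, names = FALSE)
  p995 <- stats::quantile(null_acc, 0.995, names = FALSE)
  grade <- if (obs > p995) "P<0.01" else if (obs > p975) "P<0.05" else "ns"
  list(observed_pct = obs, null_pct = null_acc,
       null_mean_pct = mean(null_acc), p975 = p975, p995 = p995,
       grade = grade, phase = phase, n_shuffles = n_shuffles)
}

#' Cross-phase decoding (shared neural codes between phases)
#'
#' Trains the decoder on one task phase and tests it on others, using the
#' same leave-one-out folds as within-phase decoding: in each fold the
#' model is fit on the training phase's rows of the training trials and
#' applied to each test phase's row of the held-out trial, so training on
#' a phase and testing on the same phase reproduces [loo_cv_decode()]
#' exactly, and same-trial leakage is impossible by construction.
#'
#' @param pr A [phase_average()] result.
#' @param train_phase Phase providing training rows.
#' @param test_phases Phases to test on (default: all phases).
#' @param classes,var_threshold Passed to the decoder.
#' @return Named numeric vector: accuracy (%) per test phase.
#' @export
cross_phase_decode <- function(pr, train_phase,
                               test_phases = names(pr$phases),
                               classes = NULL, var_threshold = 0.95) {
  stopifnot(inherits(pr, "phase_rates"))
  xtr <- pr$phases[[train_phase]]
  if (is.null(xtr)) stop("cross_phase_decode: unknown phase ", train_phase)
  bad <- setdiff(test_phases, names(pr$phases))
  if (length(bad))
    stop("cross_phase_decode: unknown test phase(s): ",
         paste(bad, collapse = ", "))
  labels <- pr$labels$word
  if (is.null(classes)) classes <- sort(unique(labels))
  n <- nrow(xtr)
  hits <- matrix(0, n, length(test_phases),
                 dimnames = list(NULL, test_phases))
  for (i in seq_len(n)) {
    m <- train_decoder(xtr[-i, , drop = FALSE], labels[-i], classes,
                       var_threshold)
    for (ph in test_phases)
      hits[i, ph] <- predict(m, pr$phases[[ph]][i, ]) == labels[i]
  }
  100 * colMeans(hits)
}

#' Cross-phase accuracy matrix over sessions, with paired comparisons
#'
#' Runs [cross_phase_decode()] for every training phase on every session,
#' averages the train x test accuracy matrix over sessions, and compares
#' test phases decoded with the same model by paired two-tailed t-tests
#' with Benjamini-Hochberg correction across all tested pairs.
#'
#' @param pr_list List of per-session [phase_average()] results.
#' @param train_phases,test_phases Phase sets (defaults: all phases of
#'   the first session).
#' @param classes,var_threshold Passed to the decoder.
#' @return List: `mean_matrix` (train x test mean accuracy, %),
#'   `per_session` (sessions x train x test array), `comparisons`
#'   (data.frame `train_phase`, `phase_a`, `phase_b`, `t`, `df`, `p`,
#'   `p_adj`).
#' @export
cross_phase_matrix <- function(pr_list,
                               train_phases = names(pr_list[[1]]$phases),
                               test_phases = names(pr_list[[1]]$phases),
                               classes = NULL, var_threshold = 0.95) {
  nS <- length(pr_list)
  acc <- array(NA_real_, c(nS, length(train_phases), length(test_phases)),
               dimnames = list(NULL, train_phases, test_phases))
  for (s in seq_len(nS))
    for (tp in train_phases)
      acc[s, tp, ] <- cross_phase_decode(pr_list[[s]], tp, test_phases,
                                         classes, var_threshold)
  cmp <- list()
  if (nS >= 2 && length(test_phases) >= 2) {
    for (tp in train_phases) {
      prs <- utils::combn(test_phases, 2, simplify = FALSE)
      for (pp in prs) {
        d <- acc[, tp, pp[1]] - acc[, tp, pp[2]]
        if (stats::sd(d) == 0) {
          tt <- 0; p <- 1
        } else {
          ht <- stats::t.test(acc[, tp, pp[1]], acc[, tp, pp[2]],
                              paired = TRUE)
          tt <- unname(ht$statistic); p <- ht$p.value
        }
        cmp[[length(cmp) + 1L]] <-
          data.frame(train_phase = tp, phase_a = pp[1], phase_b = pp[2],
                     t = tt, df = nS - 1L, p = p, stringsAsFactors = FALSE)
      }
    }
  }
  cmp <- if (length(cmp)) do.call(rbind, cmp) else NULL
  if (!is.null(cmp)) cmp$p_adj <- adjust_fdr(cmp$p)
  list(mean_matrix = apply(acc, c(2, 3), mean), per_session = acc,
       comparisons = cmp)
}

#' Simulated closed-loop online decoding with incremental retraining
#'
#' Emulates the online protocol: a decoder is trained on the
#' internal-speech rates of an initial (written-cue) training block, each
#' trial of the first online run is classified once, then the run's trials
#' are added to the training set and the decoder retrained before the next
#' run. Reports per-run accuracy and the training budget in seconds of
#' internal-speech data per word (trials per word times the internal-phase
#' duration: 16 trials of 1.5 s give 24 s). Optionally grades each run
#' against a shuffle null (labels of the accumulated training set
#' permuted, decoder retrained, run reclassified; the online protocol used
#' 1,000 repetitions).
#'
#' @param train_x,train_labels Initial training block: trials x units
#'   internal-phase rates and their word labels.
#' @param runs List of online runs, each a list with elements `x`
#'   (trials x units) and `labels`.
#' @param classes Class order (default sorted labels of the training set).
#' @param internal_duration Internal-phase duration in seconds (1.5).
#' @param var_threshold PCA cumulative-variance threshold.
#' @param n_shuffles Shuffle repetitions per run for significance grading;
#'   0 (default) skips grading.
#' @param seed Integer seed for the shuffles.
#' @return Object of class `online_result`: `per_run` data.frame (`run`,
#'   `n_train_trials`, `train_trials_per_word`, `train_seconds_per_word`,
#'   `n_trials`, `accuracy_pct`, and grading columns when requested),
#'   `overall_accuracy_pct`, `confusion`.
#' @export
simulate_online <- function(train_x, train_labels, runs,
                            classes = sort(unique(train_labels)),
                            internal_duration = 1.5,
                            var_threshold = 0.95,
                            n_shuffles = 0, seed = 1L) {
  if (!length(runs)) stop("simulate_online: need at least one run")
  for (r in runs)
    if (!nrow(as.matrix(r$x))) stop("simulate_online: empty run")
  rs <- local_rng(seed)
  acc_x <- as.matrix(train_x)
  acc_l <- as.character(train_labels)
  rows <- list()
  all_pred <- character(0)
  all_true <- character(0)
  for (r in seq_along(runs)) {
    xr <- as.matrix(runs[[r]]$x)
    lr <- as.character(runs[[r]]$labels)
    per_word <- nrow(acc_x) / length(classes)
    model <- train_decoder(acc_x, acc_l, classes, var_threshold)
    pred <- predict(model, xr)
    acc_pct <- 100 * mean(pred == lr)
    row <- data.frame(run = r, n_train_trials = nrow(acc_x),
                      train_trials_per_word = per_word,
                      train_seconds_per_word = per_word * internal_duration,
                      n_trials = nrow(xr), accuracy_pct = acc_pct)
    if (n_shuffles > 0) {
      null_acc <- vapply(seq_len(n_shuffles), function(s) {
        ms <- train_decoder(acc_x, sample(acc_l), classes, var_threshold)
        100 * mean(predict(ms, xr) == lr)
      }, 0)
      row$null_mean_pct <- mean(null_acc)
      p975 <- stats::quantile(null_acc, 0.975, names = FALSE)
      p995 <- stats::quantile(null_acc, 0.995, names = FALSE)
      row$grade <- if (acc_pct > p995) "P<0.01" else
        if (acc_pct > p975) "P<0.05" else "ns"
    }
    rows[[r]] <- row
    all_pred <- c(all_pred, pred)
    all_true <- c(all_true, lr)
    acc_x <- rbind(acc_x, xr)              # retrain after each run
    acc_l <- c(acc_l, lr)
  }
  per_run <- do.call(rbind, rows)
  structure(list(per_run = per_run,
                 overall_accuracy_pct = 100 * mean(all_pred == all_true),
                 confusion = unclass(table(factor(all_true, classes),
                                           factor(all_pred, classes)))),
            class = "online_result")
}

#' @export
print.online_result <- function(x, ...) {
  cat("Simulated online decoding\n")
  print(x$per_run, row.names = FALSE)
  cat(sprintf("overall accuracy: %.1f%%\n", x$overall_accuracy_pct))
  invisible(x)
}
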