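# Synthetic feature matrices with class structure.
clouds <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  K <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    sweep(matrix(stats::rnorm(n_per * ncol(centers), sd = sd),
                 n_per), 2, centers[k, ], `+`)))
  list(x = x, y = rep(rownames(centers), each = n_per))
}

as_phase_rates <- function(x, y, phase = "internal") {
  structure(list(phases = stats::setNames(list(x), phase),
                 labels = data.frame(trial_id = seq_along(y), word = y,
                                     cue_modality = "written",
                                     session_id = "s",
                                     stringsAsFactors = FALSE)),
            class = "phase_rates")
}

test_that("the decoder separates well-separated classes", {
  ctr <- matrix(c(0, 0, 20, 0, 0, 20), 3, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), NULL))
  d <- clouds(10, ctr, sd = 0.5, seed = 2)
  m <- train_decoder(d$x[-c(1, 11, 21), ], d$y[-c(1, 11, 21)],
                     classes = c("a", "b", "c"))
  expect_equal(predict(m, d$x[c(1, 11, 21), ]), c("a", "b", "c"))
})

test_that("variance threshold 1 keeps every component", {
  set.seed(3)
  x <- matrix(stats::rnorm(40 * 6), 40)
  y <- rep(c("a", "b"), 20)
  m <- train_decoder(x, y, var_threshold = 1)
  expect_equal(m$q, 6)
  m95 <- train_decoder(x, y, var_threshold = 0.95)
  expect_lte(m95$q, 6)
})

test_that("predictions match a brute-force discriminant oracle", {
  set.seed(7)
  ctr <- matrix(stats::rnorm(3 * 5, sd = 2), 3, 5,
                dimnames = list(c("a", "b", "c"), NULL))
  d <- clouds(8, ctr, sd = 1.5, seed = 8)
  test_idx <- c(1, 5, 9, 13, 17, 21)
  xtr <- d$x[-test_idx, ]; ytr <- d$y[-test_idx]
  xte <- d$x[test_idx, ]
  m <- train_decoder(xtr, ytr, classes = c("a", "b", "c"),
                     var_threshold = 1)
  expect_equal(predict(m, xte),
               oracle_pca_lda_predict(xtr, ytr, xte, c("a", "b", "c"),
                                      var_threshold = 1))
  # and with the 95% PCA truncation
  m95 <- train_decoder(xtr, ytr, classes = c("a", "b", "c"))
  expect_equal(predict(m95, xte),
               oracle_pca_lda_predict(xtr, ytr, xte, c("a", "b", "c")))
})

test_that("leave-one-out equals a naive per-fold re-fit oracle", {
  set.seed(12)
  ctr <- matrix(stats::rnorm(3 * 4, sd = 1.5), 3, 4,
                dimnames = list(c("a", "b", "c"), NULL))
  d <- clouds(8, ctr, sd = 2, seed = 13)       # 24 trials
  pr <- as_phase_rates(d$x, d$y)
  res <- loo_cv_decode(pr, "internal", classes = c("a", "b", "c"))
  pred_oracle <- vapply(seq_len(24), function(i)
    oracle_pca_lda_predict(d$x[-i, ], d$y[-i], d$x[i, ],
                           c("a", "b", "c")), "")
  expect_equal(res$predicted, pred_oracle)
  expect_equal(res$accuracy_pct, 100 * mean(pred_oracle == d$y))
  # confusion rows sum to the per-class trial counts
  expect_equal(unname(rowSums(res$confusion)), rep(8L, 3))
  expect_equal(sum(diag(res$confusion)) / sum(res$confusion) * 100,
               res$accuracy_pct)
})

test_that("a held-out trial's features never reach the fold model", {
  set.seed(21)
  x <- matrix(stats::rnorm(30 * 5), 30)
  y <- rep(c("a", "b", "c"), 10)
  for (i in c(1, 15, 30)) {
    m1 <- train_decoder(x[-i, ], y[-i], classes = c("a", "b", "c"))
    x2 <- x
    x2[i, ] <- 1e6                     # corrupt the held-out trial
    m2 <- train_decoder(x2[-i, ], y[-i], classes = c("a", "b", "c"))
    expect_identical(m1, m2)
  }
})

test_that("labels encoded in one feature decode perfectly", {
  y <- rep(c("a", "b", "c", "d"), each = 6)
  x <- cbind(as.numeric(factor(y)) * 10,
             matrix(stats::rnorm(24 * 3, sd = 0.1), 24))
  pr <- as_phase_rates(x, y)
  expect_equal(loo_cv_decode(pr, "internal")$accuracy_pct, 100)
})

test_that("shuffle significance grades against the null percentiles", {
  ctr <- matrix(c(0, 0, 12, 0, 0, 12, 12, 12), 4, 2, byrow = TRUE,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  d <- clouds(6, ctr, sd = 1, seed = 31)
  pr <- as_phase_rates(d$x, d$y)
  sh <- shuffle_significance(pr, "internal", n_shuffles = 60, seed = 5)
  expect_equal(sh$grade, "P<0.01")       # separable: above every null value
  expect_true(sh$observed_pct > max(sh$null_pct))
  expect_length(sh$null_pct, 60)
  # permutation null centers near chance, 25% for four balanced classes
  expect_lt(abs(sh$null_mean_pct - 25), 6)
  expect_error(shuffle_significance(pr, "internal", n_shuffles = 0), ">= 1")
})

test_that("cross-phase decoding is consistent with within-phase LOO", {
  set.seed(41)
  ctr <- matrix(stats::rnorm(4 * 6, sd = 3), 4, 6,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  d <- clouds(6, ctr, sd = 2, seed = 42)
  # phase B: byte-identical; phase C: independent class code
  ctr2 <- matrix(stats::rnorm(4 * 6, sd = 3), 4, 6,
                 dimnames = list(c("a", "b", "c", "d"), NULL))
  d2x <- clouds(6, ctr2, sd = 2, seed = 43)$x
  pr <- structure(list(
    phases = list(A = d$x, B = d$x, C = d2x),
    labels = data.frame(trial_id = seq_along(d$y), word = d$y,
                        cue_modality = "written", session_id = "s",
                        stringsAsFactors = FALSE)),
    class = "phase_rates")
  acc <- cross_phase_decode(pr, "A", c("A", "B", "C"))
  expect_equal(unname(acc["A"]),
               loo_cv_decode(pr, "A")$accuracy_pct)
  expect_equal(unname(acc["A"]), unname(acc["B"]))   # identical data
  # independently drawn class means: near chance, while within-phase high
  expect_gt(acc["A"], 60)
  expect_lt(acc["C"], 55)
  expect_gt(loo_cv_decode(pr, "C")$accuracy_pct, 60)
})

test_that("online simulation accounts training time and accumulates data", {
  set.seed(51)
  words8 <- paste0("w", 1:8)
  ctr <- matrix(stats::rnorm(8 * 10, sd = 4), 8, 10,
                dimnames = list(words8, NULL))
  train <- clouds(16, ctr, sd = 2, seed = 52)       # 16 trials per word
  runs <- lapply(1:3, function(r) {
    d <- clouds(4, ctr, sd = 2, seed = 52 + r)
    list(x = d$x, labels = d$y)
  })
  res <- simulate_online(train$x, train$y, runs, classes = words8)
  # 16 repetitions of the 1.5-s internal phase = 24 s of data per word
  expect_equal(res$per_run$train_seconds_per_word[1], 24)
  expect_equal(res$per_run$n_train_trials, c(128, 160, 192))
  expect_equal(res$per_run$train_trials_per_word, c(16, 20, 24))
  expect_gt(res$overall_accuracy_pct, 50)
  expect_equal(sum(res$confusion), 96)
  expect_error(simulate_online(train$x, train$y,
                               list(list(x = train$x[0, ],
                                         labels = character(0)))),
               "empty run")
})

test_that("online decoding of a zero-signal stream stays at chance", {
  set.seed(61)
  words8 <- paste0("w", 1:8)
  noise <- function(n_per, seed) {
    set.seed(seed)
    list(x = matrix(stats::rnorm(8 * n_per * 12), 8 * n_per),
         y = rep(words8, each = n_per))
  }
  tr <- noise(12, 62)
  runs <- lapply(1:3, function(r) {
    d <- noise(6, 62 + r)
    list(x = d$x, labels = d$y)
  })
  res <- simulate_online(tr$x, tr$y, runs, classes = words8)
  # 144 test trials at chance 12.5%: stay within ~4 binomial SDs
  se <- sqrt(0.125 * 0.875 / 144) * 100
  expect_lt(abs(res$overall_accuracy_pct - 12.5), 4 * se)
  # accuracy trend over runs has non-negative slope for tuned streams
  set.seed(63)
  d_ctr <- matrix(stats::rnorm(8 * 12, sd = 2.5), 8, 12,
                  dimnames = list(words8, NULL))
  tr2 <- clouds(4, d_ctr, sd = 3, seed = 64)
  runs2 <- lapply(1:5, function(r) {
    d <- clouds(4, d_ctr, sd = 3, seed = 64 + r)
    list(x = d$x, labels = d$y)
  })
  res2 <- simulate_online(tr2$x, tr2$y, runs2, classes = words8)
  slope <- stats::coef(stats::lm(accuracy_pct ~ run,
                                 data = res2$per_run))[2]
  expect_gte(slope, 0)
})

test_that("decoder predictions agree with an established LDA implementation", {
  # full-rank PCA is an invertible rotation, so discriminant predictions
  # must match MASS::lda with equal priors on the raw features
  set.seed(71)
  ctr <- matrix(stats::rnorm(4 * 6, sd = 2.5), 4, 6,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  d <- clouds(9, ctr, sd = 2, seed = 72)
  test_idx <- seq(1, 36, by = 4)
  xtr <- d$x[-test_idx, ]; ytr <- d$y[-test_idx]
  m <- train_decoder(xtr, ytr, classes = c("a", "b", "c", "d"),
                     var_threshold = 1)
  ref <- MASS::lda(xtr, grouping = factor(ytr, c("a", "b", "c", "d")),
                   prior = rep(0.25, 4))
  got <- predict(m, d$x[test_idx, ])
  want <- as.character(predict(ref, d$x[test_idx, ])$class)
  expect_equal(got, want)
})
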