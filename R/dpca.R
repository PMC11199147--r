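#' Build a balanced trial tensor for population analyses
#'
#' Arranges smoothed firing rates into the array `X[n, t, c, w, k]`
#' (neurons x time bins x cue modalities x words x repetitions) required
#' by demixed PCA. Every (modality, word) cell is filled with its first
#' `k_target` trials in trial order; entries belonging to error trials are
#' replaced by the average firing rate of the cell's remaining `k - 1`
#' valid trials, so the tensor stays balanced without discarding cells.
#'
#' @param rates A `rate_tensor` (smoothed).
#' @param trials The matching [trial_table()] (with `error_kind` set).
#' @param k_target Repetitions per cell (defaults to the minimum cell
#'   count).
#' @return Object of class `trial_tensor`: `values` (5-d array with
#'   dimnames), `modalities`, `words`, `n_replaced`.
#' @export
build_balanced_tensor <- function(rates, trials, k_target = NULL) {
  stopifnot(inherits(rates, "rate_tensor"))
  words <- sort(unique(trials$word))
  mods <- sort(unique(trials$cue_modality))
  d <- dim(rates$values)
  cells <- split(seq_len(nrow(trials)),
                 list(mod = trials$cue_modality, word = trials$word),
                 drop = FALSE)
  sizes <- lengths(cells)
  if (any(sizes == 0))
    stop("build_balanced_tensor: empty (modality, word) cell(s)")
  if (is.null(k_target)) k_target <- min(sizes)
  if (any(sizes < k_target))
    stop("build_balanced_tensor: cell(s) with fewer than k_target trials")
  X <- array(0, dim = c(d[2], d[3], length(mods), length(words), k_target),
             dimnames = list(rates$unit_ids, NULL, mods, words, NULL))
  n_replaced <- 0L
  for (ci in seq_len(length(mods))) for (wi in seq_len(length(words))) {
    idx <- cells[[paste(mods[ci], words[wi], sep = ".")]]
    sel <- idx[seq_len(k_target)]
    valid <- trials$error_kind[sel] == "none"
    if (!any(valid))
      stop("build_balanced_tensor: cell with zero valid trials: ",
           mods[ci], "/", words[wi])
    for (k in seq_len(k_target)) {
      if (valid[k]) {
        X[, , ci, wi, k] <- rates$values[sel[k], , ]   # units x bins
      } else {
        repl <- sel[valid]
        X[, , ci, wi, k] <-
          rowMeans(aperm(rates$values[repl, , , drop = FALSE],
                         c(2, 3, 1)), dims = 2)
        n_replaced <- n_replaced + 1L
      }
    }
  }
  structure(list(values = X, modalities = mods, words = words,
                 n_replaced = n_replaced),
            class = "trial_tensor")
}

# ANOVA-style effect terms of the trial-averaged 4-d array A[n, t, c, w]:
# grand mean per neuron plus zero-mean main and interaction effects.
marg_effects <- function(A) {
  dn <- dim(A)
  grand <- rowMeans(A, dims = 1)
  m_t <- rowMeans(A, dims = 2)                       # n x t
  m_c <- rowMeans(aperm(A, c(1, 3, 2, 4)), dims = 2) # n x c
  m_w <- rowMeans(aperm(A, c(1, 4, 2, 3)), dims = 2) # n x w
  m_tc <- rowMeans(A, dims = 3)                      # n x t x c
  m_tw <- rowMeans(aperm(A, c(1, 2, 4, 3)), dims = 3) # n x t x w
  m_cw <- rowMeans(aperm(A, c(1, 3, 4, 2)), dims = 3) # n x c x w
  eff_t <- sweep(m_t, 1, grand)
  eff_c <- sweep(m_c, 1, grand)
  eff_w <- sweep(m_w, 1, grand)
  eff_tc <- sweep(m_tc, 1, grand) -
    array(eff_t, dim(m_tc)) -
    aperm(array(eff_c, c(dn[1], dn[3], dn[2])), c(1, 3, 2))
  eff_tw <- sweep(m_tw, 1, grand) -
    array(eff_t, dim(m_tw)) -
    aperm(array(eff_w, c(dn[1], dn[4], dn[2])), c(1, 3, 2))
  eff_cw <- sweep(m_cw, 1, grand) -
    array(eff_c, dim(m_cw)) -
    aperm(array(eff_w, c(dn[1], dn[4], dn[3])), c(1, 3, 2))
  full <- function(x, dims_present, dn) {
    perm <- c(dims_present, setdiff(seq_along(dn), dims_present))
    aperm(array(x, dn[perm]), order(perm))
  }
  F_t <- full(eff_t, c(1, 2), dn)          # constant over c, w
  F_c <- full(eff_c, c(1, 3), dn)
  F_w <- full(eff_w, c(1, 4), dn)
  F_tc <- full(eff_tc, c(1, 2, 3), dn)
  F_tw <- full(eff_tw, c(1, 2, 4), dn)
  F_cw <- full(eff_cw, c(1, 3, 4), dn)
  resid <- A - array(grand, dn) - F_t - F_c - F_w - F_tc - F_tw - F_cw
  list(grand = grand,
       timing = F_t,
       cue = F_c + F_tc,
       word = F_w + F_tw,
       cue_word = F_cw + resid)
}

#' Marginalize a trial tensor
#'
#' Decomposes the trial tensor into the exact additive parts used by
#' demixed PCA: per-neuron mean, a timing (condition-independent) term,
#' grouped cue-modality terms, grouped word terms, the grouped
#' cue-by-word interaction, and trial-to-trial noise
#' `X[..., k] - mean_k X`. The parts reconstruct the tensor to machine
#' precision and, under the balanced design, are mutually orthogonal.
#'
#' @param tensor A [build_balanced_tensor()] result.
#' @return Object of class `marginalization_set`: `mean` (per-neuron
#'   grand mean), `timing`, `cue`, `word`, `cue_word` (4-d arrays over
#'   neurons x time x modality x word) and `noise` (5-d array including
#'   the repetition axis).
#' @export
marginalize <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  X <- tensor$values
  dn <- dim(X)
  A <- rowMeans(X, dims = 4)               # average over repetitions
  eff <- marg_effects(A)
  noise <- X - array(A, dn)
  structure(list(mean = eff$grand, timing = eff$timing, cue = eff$cue,
                 word = eff$word, cue_word = eff$cue_word, noise = noise,
                 dims = dn),
            class = "marginalization_set")
}

#' Reconstruction error of a marginalization set
#'
#' Maximum absolute difference between the summed marginalization parts
#' and the original tensor (identically zero up to floating point).
#'
#' @param ms A [marginalize()] result.
#' @param tensor The tensor it was computed from.
#' @return Scalar, `max |reconstruction - X|`.
#' @export
marginalization_error <- function(ms, tensor) {
  dn <- ms$dims
  rec4 <- array(ms$mean, dn[1:4]) + ms$timing + ms$cue + ms$word +
    ms$cue_word
  rec <- array(rec4, dn) + ms$noise
  max(abs(rec - tensor$values))
}

# Flatten a (n, t, c, w) array to the n x (t*c*w) matrix used in the
# regression form of the dPCA loss.
flat_ntcw <- function(A) matrix(A, nrow = dim(A)[1])

# Pseudoinverse of a symmetric PSD matrix (rank-deficient safe, so the
# ridge solve stays defined at lambda = 0).
psolve_sym <- function(G) {
  eg <- eigen(G, symmetric = TRUE)
  pos <- eg$values > max(eg$values[1], 0) * 1e-12
  if (!any(pos)) return(matrix(0, nrow(G), ncol(G)))
  eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
}

#' Fit demixed PCA by reduced-rank ridge regression
#'
#' For each marginalization `phi`, finds encoder `F_phi` (neurons x q)
#' and decoder `D_phi` (q x neurons) minimizing
#' `||X_phi - F_phi D_phi X||^2 + mu ||F_phi D_phi||^2` with
#' `mu = (lambda ||X||)^2`, where `X` is the trial-averaged, per-neuron
#' mean-centered data matrix and `||.||` the Frobenius norm. The solution
#' is the analytic reduced-rank ridge construction: the full-rank ridge
#' solution `X_phi X' (X X' + mu I)^{-1}`, truncated to rank q through
#' the SVD of its fitted values. Encoder columns are orthonormal;
#' components are ordered by captured variance.
#'
#' @param tensor A [build_balanced_tensor()] result.
#' @param marginalizations Which parts to fit (default timing, cue, word,
#'   cue_word; cue parts are skipped automatically with a single
#'   modality).
#' @param lambda Ridge scale; `mu = (lambda * ||X||_F)^2`.
#' @param q Components per marginalization.
#' @return Object of class `dpca_model`: per-marginalization `F`
#'   (encoder), `D` (decoder), `comp_var` (captured variance per
#'   component); plus `lambda`, `mu`, `q`, `dims`, `center`.
#' @export
fit_dpca <- function(tensor,
                     marginalizations = c("timing", "cue", "word",
                                          "cue_word"),
                     lambda = 0, q = 3) {
  stopifnot(inherits(tensor, "trial_tensor"), lambda >= 0, q >= 1)
  dn <- dim(tensor$values)
  if (dn[3] < 2)
    marginalizations <- setdiff(marginalizations, c("cue", "cue_word"))
  A <- rowMeans(tensor$values, dims = 4)
  eff <- marg_effects(A)
  X <- flat_ntcw(sweep(A, 1, eff$grand))
  mu <- (lambda * norm(X, "F"))^2
  Ginv <- psolve_sym(tcrossprod(X) + diag(mu, nrow(X)))
  parts <- list()
  for (phi in marginalizations) {
    Xphi <- flat_ntcw(eff[[phi]])
    W_full <- Xphi %*% t(X) %*% Ginv       # full-rank ridge solution
    M <- W_full %*% X
    sv <- svd(M)
    r <- sum(sv$d > max(sv$d[1], 1e-300) * 1e-12)
    qq <- min(q, max(r, 1))
    U <- sv$u[, seq_len(qq), drop = FALSE]
    D <- t(U) %*% W_full
    comp_var <- rowSums((D %*% X)^2)
    parts[[phi]] <- list(F = U, D = D, comp_var = comp_var)
  }
  structure(list(parts = parts, lambda = lambda, mu = mu, q = q,
                 dims = dn, center = eff$grand,
                 marginalizations = marginalizations),
            class = "dpca_model")
}

#' In-sample dPCA loss of a fitted model
#'
#' Evaluates `||X_phi - F D X||^2 + mu ||F D||^2` summed over
#' marginalizations, on the tensor used for fitting (or another tensor
#' with the same dimensions).
#'
#' @param model A [fit_dpca()] result.
#' @param tensor A `trial_tensor`.
#' @return Scalar loss.
#' @export
dpca_loss <- function(model, tensor) {
  A <- rowMeans(tensor$values, dims = 4)
  eff <- marg_effects(A)
  X <- flat_ntcw(sweep(A, 1, eff$grand))
  tot <- 0
  for (phi in names(model$parts)) {
    p <- model$parts[[phi]]
    FD <- p$F %*% p$D
    tot <- tot + norm(flat_ntcw(eff[[phi]]) - FD %*% X, "F")^2 +
      model$mu * norm(FD, "F")^2
  }
  tot
}

#' Select the dPCA ridge scale by cross-validation over trials
#'
#' Splits repetitions within every (modality, word) cell into folds
#' (tenfold by default; reduced when fewer repetitions are available),
#' fits the model on the training repetitions' averages, and scores each
#' candidate `lambda` by the held-out marginalization reconstruction
#' error `sum_phi ||X_phi^test - F_phi D_phi X^test||^2` summed over
#' folds. Deterministic given the seed.
#'
#' @param tensor A [build_balanced_tensor()] result with >= 2
#'   repetitions per cell.
#' @param lambdas Numeric candidate grid.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed for the within-cell fold assignment.
#' @param q Components per marginalization.
#' @return List: `lambda` (the minimizer), `cv_error` (named vector over
#'   the grid), `folds`.
#' @export
select_lambda <- function(tensor, lambdas, folds = 10, seed = 1L, q = 3) {
  stopifnot(inherits(tensor, "trial_tensor"))
  if (!length(lambdas)) stop("select_lambda: empty lambda grid")
  dn <- dim(tensor$values)
  K <- dn[5]
  if (K < 2) stop("select_lambda: need >= 2 repetitions per cell")
  folds <- min(folds, K)
  rs <- local_rng(seed)
  # per-cell permutation of repetition indices -> fold ids, stratified
  fold_id <- array(0L, dim = c(dn[3], dn[4], K))
  for (ci in seq_len(dn[3])) for (wi in seq_len(dn[4]))
    fold_id[ci, wi, ] <- ((sample.int(K) - 1L) %% folds) + 1L
  marg_names <- if (dn[3] < 2) c("timing", "word", "cue_word") else
    c("timing", "cue", "word", "cue_word")
  if (dn[3] < 2) marg_names <- setdiff(marg_names, c("cue", "cue_word"))
  err <- stats::setNames(numeric(length(lambdas)), as.character(lambdas))
  for (f in seq_len(folds)) {
    Atr <- array(0, dn[1:4])
    Ate <- array(NA_real_, dn[1:4])
    for (ci in seq_len(dn[3])) for (wi in seq_len(dn[4])) {
      te <- which(fold_id[ci, wi, ] == f)
      tr <- setdiff(seq_len(K), te)
      Atr[, , ci, wi] <- rowMeans(tensor$values[, , ci, wi, tr,
                                                drop = FALSE], dims = 2)
      if (length(te))
        Ate[, , ci, wi] <- rowMeans(tensor$values[, , ci, wi, te,
                                                  drop = FALSE], dims = 2)
    }
    if (anyNA(Ate)) next                   # fold empty in some cell: skip
    eff_tr <- marg_effects(Atr)
    Xtr <- flat_ntcw(sweep(Atr, 1, eff_tr$grand))
    eff_te <- marg_effects(Ate)
    Xte <- flat_ntcw(sweep(Ate, 1, eff_te$grand))
    nX <- norm(Xtr, "F")
    XX <- tcrossprod(Xtr)
    for (li in seq_along(lambdas)) {
      mu <- (lambdas[li] * nX)^2
      Ginv <- psolve_sym(XX + diag(mu, nrow(Xtr)))
      for (phi in marg_names) {
        W_full <- flat_ntcw(eff_tr[[phi]]) %*% t(Xtr) %*% Ginv
        sv <- svd(W_full %*% Xtr)
        qq <- min(q, sum(sv$d > max(sv$d[1], 1e-300) * 1e-12))
        U <- sv$u[, seq_len(max(qq, 1)), drop = FALSE]
        FD <- U %*% (t(U) %*% W_full)
        err[li] <- err[li] +
          norm(flat_ntcw(eff_te[[phi]]) - FD %*% Xte, "F")^2
      }
    }
  }
  list(lambda = lambdas[which.min(err)], cv_error = err, folds = folds)
}

#' Explained-variance ledger and decoder-axis projections
#'
#' Reports the share of total (per-neuron mean-removed) tensor variance
#' carried by each marginalization (timing, cue modality, word,
#' cue-by-word, noise; the shares sum to 1 under the balanced design) and
#' the per-component variance captured by the fitted axes, and projects
#' the trial-averaged data onto each decoder axis to give per-condition
#' time courses.
#'
#' @param model A [fit_dpca()] result.
#' @param tensor The `trial_tensor` it was fitted to.
#' @return List: `variance_shares` (named, sums to 1 with `noise`),
#'   `component_var` (per marginalization), `projections` (per
#'   marginalization: array components x time x modality x word).
#' @export
variance_and_projections <- function(model, tensor) {
  stopifnot(inherits(model, "dpca_model"), inherits(tensor, "trial_tensor"))
  dn <- dim(tensor$values)
  ms <- marginalize(tensor)
  tot <- sum((tensor$values - array(ms$mean, dn))^2)
  K <- dn[5]
  shares <- c(timing = K * sum(ms$timing^2) / tot,
              cue = K * sum(ms$cue^2) / tot,
              word = K * sum(ms$word^2) / tot,
              cue_word = K * sum(ms$cue_word^2) / tot,
              noise = sum(ms$noise^2) / tot)
  A <- rowMeans(tensor$values, dims = 4)
  X <- flat_ntcw(sweep(A, 1, ms$mean))
  proj <- lapply(model$parts, function(p) {
    array(p$D %*% X, dim = c(nrow(p$D), dn[2], dn[3], dn[4]),
          dimnames = list(NULL, NULL, tensor$modalities, tensor$words))
  })
  list(variance_shares = shares,
       component_var = lapply(model$parts, `[[`, "comp_var"),
       projections = proj)
}
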