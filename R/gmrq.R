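## GMRQ cross-validated model selection.
##
## The generalized matrix Rayleigh quotient scores how slowly the leading
## eigenvectors of a training MSM decorrelate on held-out data:
##   score = trace[ (A' Cbar_test A) (A' S_test A)^-1 ]
## with A the first m training eigenvectors expressed in the state-indicator
## basis, and Cbar/S the symmetrized lagged-correlation and instantaneous
## overlap matrices of the test state sequences at the MSM lag. The training
## eigenvectors used here are those of the variational (symmetrized-count)
## estimator, for which the self-scored value equals the sum of the first m
## training eigenvalues exactly; the reported m includes the stationary
## eigenvector (lambda_1 = 1).

#' Random trajectory-level train/test splits
#'
#' @param trajectory_ids vector of trajectory identifiers (>= 2).
#' @param test_fraction fraction of trajectories held out, in (0, 1).
#' @param n_repeats number of independent splits.
#' @param seed integer seed.
#' @return list of splits, each a list with `train`, `test`, `repeat_id`,
#'   `seed`.
#' @export
shuffle_split <- function(trajectory_ids, test_fraction = 0.5, n_repeats = 5,
                          seed = 1L) {
  if (length(trajectory_ids) < 2) stop_memsm("need >= 2 trajectories to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_memsm("test_fraction must be in (0, 1), got %g", test_fraction)
  n_test <- max(1L, min(length(trajectory_ids) - 1L,
                        round(test_fraction * length(trajectory_ids))))
  with_seed(seed, lapply(seq_len(n_repeats), function(r) {
    te <- sort(sample(seq_along(trajectory_ids), n_test))
    list(train = trajectory_ids[-te], test = trajectory_ids[te],
         repeat_id = r, seed = as.integer(seed))
  }))
}

## Empirical symmetrized correlation and overlap matrices of state
## sequences at the given lag, over the full 1..k state space.
state_correlation_matrices <- function(states, lag_frames, k) {
  C <- matrix(0, k, k)
  for (s in states) {
    if (length(s) <= lag_frames) next
    i <- s[1:(length(s) - lag_frames)]; j <- s[(lag_frames + 1):length(s)]
    C <- C + matrix(tabulate((i - 1L) * k + j, k * k), k, k, byrow = TRUE)
  }
  N <- sum(C)
  if (N == 0) stop_memsm("no lagged pairs in state sequences")
  Cbar <- (C + t(C)) / (2 * N)
  Svec <- (rowSums(C) + colSums(C)) / (2 * N)
  list(Cbar = Cbar, S = Svec, n_pairs = N, counts = C)
}

## First m eigenvectors (state-indicator basis, S-orthonormal) of the
## variational symmetrized estimator built from a raw count matrix on its
## active set; rows for inactive states are zero.
variational_eigenvectors <- function(C_active, active, k, m) {
  N <- sum(C_active)
  Cbar <- (C_active + t(C_active)) / (2 * N)
  Svec <- (rowSums(C_active) + colSums(C_active)) / (2 * N)
  sq <- sqrt(Svec)
  M <- Cbar / outer(sq, sq)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  m_eff <- min(m, length(active))
  V <- e$vectors[, seq_len(m_eff), drop = FALSE] / sq
  A <- matrix(0, k, m_eff)
  A[active, ] <- V
  list(A = A, values = e$values[seq_len(m_eff)], m_eff = m_eff)
}

#' GMRQ score of a trained MSM on test state sequences
#'
#' @param train_msm an `msm_model` (its raw count matrix and active set
#'   define the training eigenvectors).
#' @param cluster_model the `cluster_model` shared by train and test
#'   assignments (defines the state space size).
#' @param test_states list of integer state sequences assigned with
#'   `cluster_model`.
#' @param m number of eigenvectors scored (stationary eigenvector included);
#'   default 6.
#' @param frame_interval ns between frames (needed to convert the MSM lag to
#'   frames).
#' @return numeric score, bounded above by m; attributes `m_eff` (number of
#'   eigenvectors actually available) and `rank` (rank of the test overlap;
#'   a degraded-rank warning is emitted when it is deficient).
#' @export
gmrq_score <- function(train_msm, cluster_model, test_states, m = 6,
                       frame_interval) {
  k <- cluster_model$k
  lag_frames <- round(train_msm$tau / frame_interval)
  ve <- variational_eigenvectors(train_msm$C, train_msm$active, k, m)
  if (ve$m_eff < m)
    warn_memsm("only %d eigenvectors available (m = %d requested)", ve$m_eff, m)
  tc <- state_correlation_matrices(test_states, lag_frames, k)
  A <- ve$A
  num <- t(A) %*% tc$Cbar %*% A
  den <- t(A) %*% (tc$S * A)
  pv <- pinv_with_rank(den)
  if (pv$rank < ve$m_eff)
    warn_memsm("test overlap matrix rank %d < %d; score computed with pseudo-inverse",
               pv$rank, ve$m_eff)
  score <- sum(diag(num %*% pv$inv))
  attr(score, "m_eff") <- ve$m_eff
  attr(score, "rank") <- pv$rank
  score
}

#' Grid search over featurizations and (t, g, k) hyperparameters
#'
#' For every featurization and hyperparameter combination: fit tICA and
#' mini-batch k-means on the training trajectories of each split, build the
#' training MSM, and score the held-out trajectories with [gmrq_score()].
#' Individual fit failures are recorded (with the reason) and skipped, not
#' fatal. Fully deterministic given `seed`.
#'
#' @param features_by_spec named list: for each featurization id, a list of
#'   per-trajectory feature matrices.
#' @param t_grid tICA lag times, ns (default within the 0.5-5 ns range).
#' @param g_grid regularization strengths (default log-spaced in
#'   `[1e-10, 1e-1]`).
#' @param k_grid numbers of cluster states.
#' @param tau MSM lag, ns; default 4.5.
#' @param m eigenvectors scored; default 6.
#' @param n_components tICA components kept; default 4.
#' @param splits list from [shuffle_split()]; trajectory ids must index
#'   `features_by_spec[[i]]`.
#' @param seed base seed for clustering.
#' @param batch_size,n_iter mini-batch k-means parameters.
#' @return data frame of class `gmrq_results` with one row per
#'   (featurization, t, g, k, split): `train_score`, `test_score`, `error`
#'   (NA on success); attribute `m`; sorted by descending mean test score
#'   within featurization.
#' @export
hyperparameter_search <- function(features_by_spec,
                                  t_grid = c(0.5, 2, 5),
                                  g_grid = 10^c(-1, -4, -7, -10),
                                  k_grid = c(5, 10, 20, 50),
                                  tau = 4.5, m = 6, n_components = 4,
                                  splits, seed = 1L,
                                  batch_size = 256L, n_iter = 100L) {
  stopifnot(length(t_grid) > 0, length(g_grid) > 0, length(k_grid) > 0,
            length(splits) > 0)
  rows <- list()
  combo <- 0L
  for (fid in names(features_by_spec)) {
    feats <- features_by_spec[[fid]]
    fi <- attr(feats[[1]], "frame_interval")
    for (tv in t_grid) for (gv in g_grid) for (kv in k_grid) {
      combo <- combo + 1L
      for (sp in seq_along(splits)) {
        s <- splits[[sp]]
        res <- tryCatch({
          tica <- fit_tica(feats[s$train], lag = tv, g = gv,
                           n_components = n_components)
          tics <- tica_transform(tica, feats)
          cm <- fit_minibatch_kmeans(tics[s$train], k = kv,
                                     seed = (seed + 7919L * combo) %% .Machine$integer.max,
                                     batch_size = batch_size, n_iter = n_iter)
          train_states <- assign_states(cm, tics[s$train])
          test_states <- assign_states(cm, tics[s$test])
          msm <- build_msm(train_states, tau = tau, frame_interval = fi, k = kv)
          tr_sc <- gmrq_score(msm, cm, train_states, m = m, frame_interval = fi)
          te_sc <- gmrq_score(msm, cm, test_states, m = m, frame_interval = fi)
          data.frame(featurization = fid, t = tv, g = gv, k = kv, split = sp,
                     train_score = as.numeric(tr_sc), test_score = as.numeric(te_sc),
                     error = NA_character_, stringsAsFactors = FALSE)
        }, error = function(e)
          data.frame(featurization = fid, t = tv, g = gv, k = kv, split = sp,
                     train_score = NA_real_, test_score = NA_real_,
                     error = conditionMessage(e), stringsAsFactors = FALSE))
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  attr(out, "eigenvector_convention") <- "stationary eigenvector included in m"
  class(out) <- c("gmrq_results", "data.frame")
  out
}

#' Summarize a GMRQ search by hyperparameter combination
#'
#' @param results a `gmrq_results` data frame.
#' @return data frame with one row per (featurization, t, g, k): mean train
#'   and test scores over splits, sorted by descending mean test score.
#' @export
summarize_gmrq <- function(results) {
  ok <- results[is.na(results$error), , drop = FALSE]
  if (!nrow(ok)) stop_memsm("no successful GMRQ fits to summarize")
  keys <- c("featurization", "t", "g", "k")
  agg <- stats::aggregate(ok[c("train_score", "test_score")], by = ok[keys], mean)
  names(agg)[5:6] <- c("mean_train_score", "mean_test_score")
  agg[order(-agg$mean_test_score, agg$featurization), , drop = FALSE]
}

#' Top-ranked featurizations
#'
#' Selects, per featurization, the best hyperparameter combination by mean
#' test score, then returns the top `n` featurizations; ties break
#' lexicographically on the featurization id.
#'
#' @param results a `gmrq_results` data frame.
#' @param n number of featurizations; default 5.
#' @return data frame (one row per featurization, best combination first).
#' @export
top_featurizations <- function(results, n = 5) {
  agg <- summarize_gmrq(results)
  best <- do.call(rbind, lapply(split(agg, agg$featurization), function(g)
    g[which.max(g$mean_test_score), , drop = FALSE]))
  best <- best[order(-best$mean_test_score, best$featurization), , drop = FALSE]
  if (n > nrow(best)) {
    warn_memsm("requested %d featurizations but only %d available", n, nrow(best))
    n <- nrow(best)
  }
  rownames(best) <- NULL
  utils::head(best, n)
}
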