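## State decomposition and reversible Markov state model estimation.

#' Mini-batch k-means clustering
#'
#' Clusters pooled tIC (or collective-variable) frames into k states with
#' the mini-batch k-means algorithm: random initial centers drawn from the
#' data, then per-batch nearest-center assignment and per-center running-mean
#' updates with learning rate 1/n_assigned. Deterministic given `seed`.
#'
#' @param tics list of frames x dim matrices (or one matrix).
#' @param k number of states (>= 2).
#' @param seed integer seed.
#' @param batch_size frames per mini-batch.
#' @param n_iter number of mini-batch iterations.
#' @return object of class `cluster_model`: `centers` (k x dim), `k`,
#'   `seed`, `inertia` (mean squared distance of all frames to their
#'   centers after fitting).
#' @export
fit_minibatch_kmeans <- function(tics, k, seed = 1L, batch_size = 256L,
                                 n_iter = 100L) {
  X <- if (is.list(tics) && !is.matrix(tics)) do.call(rbind, tics) else tics
  X <- as.matrix(X)
  if (k < 2) stop_memsm("k must be >= 2")
  if (nrow(X) < k) stop_memsm("fewer frames (%d) than states (%d)", nrow(X), k)
  Xu <- unique(X)
  if (nrow(Xu) < k)
    stop_memsm("only %d distinct points for k = %d", nrow(Xu), k)
  with_seed(seed, {
    centers <- Xu[sample.int(nrow(Xu), k), , drop = FALSE]
    counts <- rep(0, k)
    for (it in seq_len(n_iter)) {
      bi <- sample.int(nrow(X), min(batch_size, nrow(X)))
      B <- X[bi, , drop = FALSE]
      a <- nearest_center(B, centers)
      for (j in unique(a)) {
        pts <- B[a == j, , drop = FALSE]
        for (r in seq_len(nrow(pts))) {
          counts[j] <- counts[j] + 1
          eta <- 1 / counts[j]
          centers[j, ] <- (1 - eta) * centers[j, ] + eta * pts[r, ]
        }
      }
    }
    a <- nearest_center(X, centers)
    inertia <- sum((X - centers[a, , drop = FALSE])^2) / nrow(X)
    structure(list(centers = centers, k = as.integer(k), seed = as.integer(seed),
                   inertia = inertia), class = "cluster_model")
  })
}

## Nearest center (squared Euclidean), ties resolved to the lowest index.
nearest_center <- function(X, centers) {
  d2 <- outer(rowSums(X^2), rep(1, nrow(centers))) -
    2 * X %*% t(centers) + outer(rep(1, nrow(X)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Assign frames to cluster states
#'
#' @param model a `cluster_model`.
#' @param tics matrix or list of matrices in the clustered space.
#' @return integer state sequence (or list of sequences), states in 1..k.
#' @export
assign_states <- function(model, tics) {
  one <- function(X) {
    X <- as.matrix(X)
    if (ncol(X) != ncol(model$centers))
      stop_memsm("dimension mismatch: data %d vs centers %d", ncol(X), ncol(model$centers))
    s <- nearest_center(X, model$centers)
    attr(s, "frame_interval") <- attr(X, "frame_interval")
    s
  }
  if (is.list(tics) && !is.matrix(tics)) lapply(tics, one) else one(tics)
}

#' Sliding-window transition counts
#'
#' `C[i, j]` counts frame pairs `(t, t + lag)` with states i, j, pooled over
#' trajectories; pairs never cross trajectory boundaries.
#'
#' @param states list of integer state sequences (or one sequence).
#' @param tau MSM lag time in ns (default 4.5); rounded down to a multiple
#'   of `frame_interval` with a message if needed.
#' @param frame_interval ns between frames.
#' @param k number of states (defaults to the largest state index seen).
#' @return k x k count matrix with attribute `lag_frames`.
#' @export
count_transitions <- function(states, tau = 4.5, frame_interval, k = NULL) {
  if (!is.list(states)) states <- list(states)
  lf <- floor(tau / frame_interval + 1e-9)
  if (abs(lf * frame_interval - tau) > 1e-9)
    message(sprintf("MSM lag %g ns rounded down to %d frames (%g ns)",
                    tau, lf, lf * frame_interval))
  if (lf < 1) stop_memsm("MSM lag shorter than one frame interval")
  k <- k %||% max(vapply(states, max, 1L))
  C <- matrix(0, k, k)
  any_pairs <- FALSE
  for (s in states) {
    if (length(s) <= lf) next
    any_pairs <- TRUE
    i <- s[1:(length(s) - lf)]; j <- s[(lf + 1):length(s)]
    C <- C + matrix(tabulate((i - 1L) * k + j, k * k), k, k, byrow = TRUE)
  }
  if (!any_pairs) stop_memsm("all trajectories are shorter than the MSM lag")
  attr(C, "lag_frames") <- as.integer(lf)
  C
}

#' Largest strongly connected set of states
#'
#' States restricted to the largest strongly connected component of the
#' directed graph with an edge i -> j wherever `C[i, j] > 0` (ergodic
#' trimming: a stationary distribution is only defined on such a set).
#'
#' @param C nonnegative count matrix.
#' @return sorted integer vector of active state indices.
#' @export
largest_connected_set <- function(C) {
  if (any(C < 0)) stop_memsm("count matrix must be nonnegative")
  nz <- which(rowSums(C) + colSums(C) > 0)
  if (!length(nz)) stop_memsm("empty transition graph")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))[1]
  active <- sort(which(comp$membership == best))
  dropped <- setdiff(nz, active)
  if (length(dropped))
    message(sprintf("ergodic trimming dropped %d state(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  active
}

#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the transition matrix maximizing the trajectory likelihood
#' under the detailed-balance constraint, by the classic self-consistent
#' fixed-point iteration on the symmetrized pair counts
#' `x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)`. Detailed balance holds
#' exactly at every iterate; iteration stops when `max|T_new - T_old| <
#' tol`. The stationary distribution is `pi_i = x_i / sum(x)` and the full
#' eigensystem is computed through the symmetrized similarity transform, so
#' the spectrum is real by construction.
#'
#' @param C count matrix already restricted to a strongly connected active
#'   set (see [largest_connected_set()]); every state needs an outgoing
#'   count.
#' @param tau MSM lag time in ns.
#' @param active optional integer labels of the active states (bookkeeping
#'   only; defaults to `1:nrow(C)`).
#' @param tol convergence tolerance on `max|delta T|`; default 1e-10.
#' @param max_iter iteration cap; default 1e6.
#' @return object of class `msm_model`: `T` (row-stochastic), `pi`,
#'   `eigenvalues` (descending, `lambda_1 = 1`), `right_vectors`,
#'   `left_vectors` (pi-orthonormal), `C`, `active`, `tau`, `iterations`.
#' @export
fit_reversible_msm <- function(C, tau, active = NULL, tol = 1e-10,
                               max_iter = 1e6) {
  k <- nrow(C)
  active <- active %||% seq_len(k)
  ci <- rowSums(C)
  if (any(ci == 0)) stop_memsm("state(s) without outgoing counts: %s",
                               paste(which(ci == 0), collapse = ", "))
  X <- C + t(C)
  Tm <- X / rowSums(X)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(X)
    denom <- outer(ci / xi, ci / xi, "+")
    Xn <- (C + t(C)) / denom
    Tn <- Xn / rowSums(Xn)
    delta <- max(abs(Tn - Tm))
    X <- Xn; Tm <- Tn
    if (delta < tol) break
    if (it == max_iter)
      stop_memsm("reversible MLE did not converge: residual %.3g after %d iterations",
                 delta, it)
  }
  pi <- rowSums(X) / sum(X)
  ## symmetric similarity: M = D^1/2 T D^-1/2 has the same (real) spectrum
  sq <- sqrt(pi)
  M <- (sq * Tm) %*% diag(1 / sq, k)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  right <- e$vectors / sq   # columns: right eigenvectors of T
  left <- e$vectors * sq    # columns: left eigenvectors of T
  ## normalize: right vectors pi-orthonormal, lambda_1 vector constant +1
  for (j in seq_len(k)) {
    nrm <- sqrt(sum(pi * right[, j]^2))
    right[, j] <- right[, j] / nrm
    left[, j] <- left[, j] * nrm
    i <- which.max(abs(right[, j]))
    if (right[i, j] < 0) { right[, j] <- -right[, j]; left[, j] <- -left[, j] }
  }
  structure(list(T = Tm, pi = pi, eigenvalues = e$values,
                 right_vectors = right, left_vectors = left,
                 C = C, active = active, tau = tau, iterations = it),
            class = "msm_model")
}

#' Implied relaxation timescales
#'
#' `t_i = -tau / log(lambda_(i+1))` for the leading non-stationary
#' eigenvalues; non-positive eigenvalues yield `NA` with a message (no
#' relaxation time is defined for them).
#'
#' @param msm an `msm_model`.
#' @param n number of timescales.
#' @return numeric vector of times in ns.
#' @export
implied_timescales <- function(msm, n = 5) {
  lam <- msm$eigenvalues[-1]
  n <- min(n, length(lam))
  lam <- lam[seq_len(n)]
  out <- rep(NA_real_, n)
  ok <- lam > 0 & lam < 1
  if (any(!ok)) message(sprintf("%d eigenvalue(s) outside (0,1); timescales undefined", sum(!ok)))
  out[ok] <- -msm$tau / log(lam[ok])
  out
}

#' Convenience: counts, trimming and reversible estimation in one call
#'
#' @param states list of state sequences.
#' @param tau MSM lag, ns.
#' @param frame_interval ns between frames.
#' @param k total number of cluster states.
#' @return an `msm_model` whose `active` field maps back to original state
#'   labels; frames in trimmed states keep their labels but have no MSM
#'   weight.
#' @export
build_msm <- function(states, tau = 4.5, frame_interval, k = NULL) {
  C <- count_transitions(states, tau, frame_interval, k)
  active <- largest_connected_set(C)
  fit_reversible_msm(C[active, active, drop = FALSE], tau, active = active)
}
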