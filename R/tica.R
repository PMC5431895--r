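## Time-lagged independent component analysis with L2 (ridge) regularization.
##
## tICA finds the linear combinations of features that decorrelate most
## slowly: the generalized symmetric eigenproblem  Cbar v = lambda (C00 + gI) v,
## where C00 is the instantaneous covariance and Cbar the symmetrized
## time-lagged covariance, both accumulated over lagged frame pairs pooled
## across trajectories (pairs never cross a trajectory boundary).

#' Fit a tICA model
#'
#' @param features list of feature matrices (one per trajectory, equal
#'   column count), as produced by [featurize_dataset()].
#' @param lag tICA lag time t in ns; rounded to the nearest multiple of the
#'   frame interval with a message if not already one.
#' @param g L2 regularization strength gamma added to the diagonal of the
#'   instantaneous covariance (a ridge on the metric).
#' @param n_components number of slow components kept; default 4.
#' @return object of class `tica_model`: `mean`, `C00`, `Cbar`, `eigenvalues`
#'   (descending), `components` (columns, (C00+gI)-orthonormal, sign-fixed so
#'   each component's largest-magnitude loading is positive), `lag` (ns),
#'   `lag_frames`, `g`, `n_pairs`.
#' @export
fit_tica <- function(features, lag, g, n_components = 4) {
  if (!is.list(features)) features <- list(features)
  fi <- attr(features[[1]], "frame_interval")
  if (is.null(fi)) stop_memsm("features lack a frame_interval attribute")
  lf <- round(lag / fi)
  if (abs(lf * fi - lag) > 1e-9)
    message(sprintf("tICA lag %g ns rounded to %d frames (%g ns)", lag, lf, lf * fi))
  if (lf < 1) stop_memsm("tICA lag must be at least one frame interval")
  p <- ncol(features[[1]])

  s0 <- numeric(p); n <- 0
  S00 <- matrix(0, p, p); S0t <- matrix(0, p, p)
  used <- 0L
  for (X in features) {
    if (ncol(X) != p) stop_memsm("inconsistent feature dimension across trajectories")
    if (nrow(X) <= lf) next
    A <- X[1:(nrow(X) - lf), , drop = FALSE]
    B <- X[(lf + 1):nrow(X), , drop = FALSE]
    s0 <- s0 + colSums(A) + colSums(B)
    n <- n + 2L * nrow(A)
    S00 <- S00 + crossprod(A) + crossprod(B)
    S0t <- S0t + crossprod(A, B)
    used <- used + 1L
  }
  if (used == 0L) stop_memsm("no trajectory is longer than the tICA lag")
  if (used < length(features))
    warn_memsm("%d trajectory(ies) shorter than the lag contribute no pairs",
               length(features) - used)
  mu <- s0 / n
  C00 <- S00 / n - tcrossprod(mu)
  C0t <- S0t / (n / 2) - tcrossprod(mu)
  Cbar <- (C0t + t(C0t)) / 2

  cvar <- diag(C00)
  if (any(cvar < 1e-14) && g <= 0) {
    bad <- colnames(features[[1]])[which(cvar < 1e-14)]
    stop_memsm("constant feature column(s): %s (use g > 0 or drop them)",
               paste(bad, collapse = ", "))
  }

  eg <- generalized_eigen(Cbar, C00 + g * diag(p))
  k <- min(n_components, p)
  V <- eg$vectors[, seq_len(k), drop = FALSE]
  ## deterministic sign: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  rownames(V) <- colnames(features[[1]])
  structure(list(mean = mu, C00 = C00, Cbar = Cbar,
                 eigenvalues = eg$values[seq_len(k)], components = V,
                 lag = lf * fi, lag_frames = lf, g = g,
                 n_components = k, n_pairs = n / 2,
                 frame_interval = fi),
            class = "tica_model")
}

## Symmetric-definite generalized eigenproblem A v = lambda B v via Cholesky
## whitening; eigenvectors are B-orthonormal, eigenvalues descending.
generalized_eigen <- function(A, B) {
  L <- tryCatch(chol(B), error = function(e)
    stop_memsm("metric matrix not positive definite (%s); increase g", conditionMessage(e)))
  ## symmetric whitened matrix: L^-T A L^-1
  M <- forwardsolve(t(L), t(forwardsolve(t(L), A)))
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  vec <- backsolve(L, e$vectors)
  list(values = e$values, vectors = vec)
}

#' Project features onto tICA components
#'
#' @param model a `tica_model`.
#' @param features one feature matrix or a list of them.
#' @return frames x n_components matrix (or list of such matrices).
#' @export
tica_transform <- function(model, features) {
  one <- function(X) {
    if (ncol(X) != length(model$mean))
      stop_memsm("feature dimension %d does not match model dimension %d",
                 ncol(X), length(model$mean))
    out <- sweep(X, 2, model$mean) %*% model$components
    colnames(out) <- paste0("tic", seq_len(ncol(out)))
    attr(out, "frame_interval") <- attr(X, "frame_interval") %||% model$frame_interval
    out
  }
  if (is.list(features) && !is.matrix(features)) lapply(features, one) else one(features)
}

#' Serialize / restore a tICA model as JSON
#' @param model a `tica_model`.
#' @param path JSON path.
#' @return `path` invisibly / the restored model.
#' @export
write_tica_json <- function(model, path) {
  jsonlite::write_json(lapply(unclass(model), function(x)
    if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x)) else x),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tica_json
#' @export
read_tica_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("C00", "Cbar", "components"))
    raw[[nm]] <- matrix(raw[[nm]]$data, raw[[nm]]$dim[1], raw[[nm]]$dim[2])
  structure(raw, class = "tica_model")
}
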