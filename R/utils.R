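## Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the default generator, evaluates
#' `expr`, and restores the previous state on exit, so that seeded pipeline
#' stages never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_memsm <- function(...) stop(sprintf(...), call. = FALSE)
warn_memsm <- function(...) warning(sprintf(...), call. = FALSE)

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_memsm("non-finite values in %s", what)
  invisible(x)
}

## Minimum-image displacement components for an orthorhombic box.
## dx is a numeric vector/matrix of raw coordinate differences along one axis.
min_image <- function(dx, L) dx - L * round(dx / L)

## Minimum-image distances between one point set and another (single frame).
## a: n x 3, b: m x 3, box: length-3 or NULL (no periodicity). Returns n x m.
pairwise_dist_box <- function(a, b, box = NULL) {
  dx <- outer(a[, 1], b[, 1], "-")
  dy <- outer(a[, 2], b[, 2], "-")
  dz <- outer(a[, 3], b[, 3], "-")
  if (!is.null(box)) {
    dx <- min_image(dx, box[1]); dy <- min_image(dy, box[2]); dz <- min_image(dz, box[3])
  }
  sqrt(dx * dx + dy * dy + dz * dz)
}

## Moore-Penrose pseudo-inverse with explicit tolerance, reporting rank.
pinv_with_rank <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d, .Machine$double.eps)
  rank <- sum(keep)
  inv <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  list(inv = inv, rank = rank)
}

## Stable hash of an R object via serialization to a temp file (md5).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(md5sum(f))
}
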