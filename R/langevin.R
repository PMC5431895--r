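## Overdamped Langevin sampling of the ground-truth potential.

#' Sample trajectories on the (depth, angle) plane
#'
#' Integrates overdamped (Brownian) Langevin dynamics on the ground-truth
#' potential with the Euler-Maruyama scheme
#' `x+ = x - (D/kT) grad U(x) dt + sqrt(2 D dt) xi`, independently per
#' coordinate, for every trajectory in the configuration. Frames are recorded
#' every `frame_interval` ns (the first recorded frame is the start
#' configuration). All randomness is governed by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `cv_trajset`: list with `trajectories` (list of
#'   frames x 2 matrices, columns `d`, `theta`), `frame_interval` (ns),
#'   `seed`, and `config_hash`.
#' @export
sample_langevin <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_sub <- round(config$frame_interval / config$timestep)
  if (abs(n_sub * config$timestep - config$frame_interval) > 1e-9)
    message(sprintf("timestep rounded to frame_interval/%d = %g ns", n_sub,
                    config$frame_interval / n_sub))
  dt <- config$frame_interval / n_sub
  D <- config$diffusion; kT <- config$kT

  ## Euler-Maruyama stability: (D/kT) * max curvature * dt < 1. The largest
  ## curvature of one Gaussian well of amplitude A and width s is A/s^2 at the
  ## minimum; confinement adds 2k.
  curv <- 2 * config$confinement_strength
  for (w in config$wells) curv <- curv + w$depth / w$widths^2
  stab <- max(D / kT * curv * dt)
  if (stab >= 1)
    warn_memsm("Euler-Maruyama stability factor %.2f >= 1; decrease timestep", stab)

  bound <- config$confinement_center +
    sqrt(50 / config$confinement_strength) * 10 # divergence guard

  n_traj <- config$n_trajectories
  n_frames <- config$frames_per_trajectory
  with_seed(config$seed, {
    x <- langevin_starts(config)
    out <- array(NA_real_, c(n_frames, n_traj, 2))
    out[1, , ] <- x
    for (f in seq_len(n_frames - 1L)) {
      for (s in seq_len(n_sub)) {
        g <- potential_gradient(x, config)
        x <- x - (g * dt / kT) %*% diag(D) +
          matrix(rnorm(2 * n_traj), n_traj, 2) %*% diag(sqrt(2 * D * dt))
      }
      if (!all(is.finite(x)) ||
          any(abs(x[, 1] - config$confinement_center[1]) > bound[1] - config$confinement_center[1]) ||
          any(abs(x[, 2] - config$confinement_center[2]) > bound[2] - config$confinement_center[2]))
        stop_memsm("trajectory diverged at frame %d: timestep %g ns is too large", f + 1L, dt)
      out[f + 1L, , ] <- x
    }
    trajectories <- lapply(seq_len(n_traj), function(i) {
      m <- out[, i, , drop = FALSE]
      dim(m) <- c(n_frames, 2)
      colnames(m) <- c("d", "theta")
      m
    })
    structure(list(trajectories = trajectories,
                   frame_interval = config$frame_interval,
                   seed = config$seed,
                   config_hash = object_hash(config)),
              class = "cv_trajset")
  })
}

## Start configurations per the config's start rule; returns n_traj x 2.
langevin_starts <- function(config) {
  n <- config$n_trajectories
  if (is.matrix(config$start)) {
    if (nrow(config$start) != n || ncol(config$start) != 2)
      stop_memsm("explicit start matrix must be n_trajectories x 2")
    return(check_finite(config$start, "start matrix"))
  }
  centers <- do.call(rbind, lapply(config$wells, function(w) w$center))
  if (identical(config$start, "wells")) {
    wts <- config$start_weights %||% rep(1 / nrow(centers), nrow(centers))
    idx <- sample.int(nrow(centers), n, replace = TRUE, prob = wts)
    return(centers[idx, , drop = FALSE])
  }
  if (identical(config$start, "span")) {
    ## Even spacing along the segment through the extreme well centers,
    ## extended 20% past each end: emulates seeding from a pull across the
    ## insertion coordinate.
    o <- order(centers[, 1])
    a <- centers[o[1], ]; b <- centers[o[nrow(centers)], ]
    if (nrow(centers) == 1) { a <- b <- centers[1, ] }
    tt <- if (n == 1) 0.5 else seq(-0.2, 1.2, length.out = n)
    return(cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2])))
  }
  stop_memsm("unknown start rule '%s'", config$start)
}

#' Write / read ground-truth collective-variable trajectories as CSV
#'
#' Long format with columns `traj_id`, `frame`, `d_nm`, `theta_deg`; the
#' frame interval is stored in a `# frame_interval_ns:` header comment.
#'
#' @param cvs a `cv_trajset`.
#' @param path output CSV path.
#' @return `write_cv_csv` returns `path` invisibly; `read_cv_csv` returns a
#'   `cv_trajset`.
#' @export
write_cv_csv <- function(cvs, path) {
  stopifnot(inherits(cvs, "cv_trajset"))
  df <- do.call(rbind, lapply(seq_along(cvs$trajectories), function(i) {
    m <- cvs$trajectories[[i]]
    data.frame(traj_id = i, frame = seq_len(nrow(m)),
               d_nm = m[, "d"], theta_deg = m[, "theta"])
  }))
  con <- file(path, "w")
  writeLines(sprintf("# frame_interval_ns: %.17g", cvs$frame_interval), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_cv_csv
#' @param path CSV path written by `write_cv_csv`.
#' @export
read_cv_csv <- function(path) {
  header <- readLines(path, n = 1)
  fi <- as.numeric(sub("# frame_interval_ns:", "", header, fixed = TRUE))
  df <- read.csv(path, comment.char = "#")
  trajectories <- lapply(split(df, df$traj_id), function(g) {
    m <- cbind(d = g$d_nm, theta = g$theta_deg)
    m[order(g$frame), , drop = FALSE]
  })
  names(trajectories) <- NULL
  structure(list(trajectories = trajectories, frame_interval = fi,
                 seed = NA_integer_, config_hash = NA_character_),
            class = "cv_trajset")
}
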