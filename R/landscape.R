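## Collective variables, MSM-reweighted free-energy landscapes, basin
## free-energy differences and bootstrap confidence intervals.

#' Per-frame membrane reference frame
#'
#' Separates the lipid phosphorus atoms into two leaflets by k-means on
#' their z coordinates (k = 2, initialized at the extreme z values) and
#' returns, per frame, the membrane mid-plane `z_center` (midpoint of the
#' two leaflet mean planes) and the z of the peptide-proximal ("bottom")
#' leaflet plane.
#'
#' @param traj a [mem_trajectory()].
#' @param topo a [mem_topology()].
#' @return matrix frames x 2, columns `z_center`, `proximal_leaflet_z`.
#' @export
compute_membrane_frame <- function(traj, topo) {
  lp <- role_idx(topo, "lipid_phosphorus")
  if (length(lp) < 2) stop_memsm("need phosphorus atoms in both leaflets")
  pep <- c(protein_heavy_idx(topo, include_ligand = TRUE), role_idx(topo, "zinc"))
  out <- matrix(NA_real_, n_frames(traj), 2,
                dimnames = list(NULL, c("z_center", "proximal_leaflet_z")))
  for (f in seq_len(n_frames(traj))) {
    z <- traj$xyz[f, lp, 3]
    km <- stats::kmeans(z, centers = matrix(range(z), 2, 1))
    lo <- which.min(km$centers); hi <- which.max(km$centers)
    if (max(z[km$cluster == lo]) >= min(z[km$cluster == hi]))
      stop_memsm("leaflet separation ambiguous in frame %d (overlapping z clusters)", f)
    zc <- (km$centers[lo] + km$centers[hi]) / 2
    zpep <- mean(traj$xyz[f, pep, 3])
    prox <- if (zpep >= zc) km$centers[hi] else km$centers[lo]
    out[f, ] <- c(zc, prox)
  }
  out
}

#' Insertion depth and tilt angle collective variables
#'
#' Depth `d` is the signed distance (nm) of the binding-site centroid (mean
#' alpha-carbon position of M9, T12, L21 and V25) from the membrane
#' mid-plane along the membrane normal, positive toward the peptide-proximal
#' leaflet and beyond. The angle `theta` (degrees) is between the membrane
#' plane and the axis from the binding-site centroid to the distal centroid
#' (mean of the alpha carbons of F3, G35, N48 and the zinc), positive when
#' the distal end points away from the membrane.
#'
#' @param traj a [mem_trajectory()].
#' @param topo a [mem_topology()] containing all named alpha carbons and the
#'   zinc.
#' @return matrix frames x 4: `d`, `theta`, `z_center`,
#'   `proximal_leaflet_z`; attribute `frame_interval`.
#' @export
compute_cv <- function(traj, topo) {
  mf <- compute_membrane_frame(traj, topo)
  pep <- c(protein_heavy_idx(topo, include_ligand = TRUE), role_idx(topo, "zinc"))
  out <- matrix(NA_real_, n_frames(traj), 4,
                dimnames = list(NULL, c("d", "theta", "z_center", "proximal_leaflet_z")))
  for (f in seq_len(n_frames(traj))) {
    x <- frame_coords(traj, f)
    b <- centroid_of(topo, x, "binding")
    a <- centroid_of(topo, x, "distal")
    s <- if (mean(x[pep, 3]) >= mf[f, 1]) 1 else -1
    d <- s * (b[3] - mf[f, 1])
    axis <- a - b
    th <- asin(max(-1, min(1, s * axis[3] / sqrt(sum(axis^2))))) * 180 / pi
    out[f, ] <- c(d, th, mf[f, ])
  }
  attr(out, "frame_interval") <- traj$frame_interval
  out
}

## Per-frame (d, theta, weight) table under MSM reweighting: each frame in
## an active state s gets weight pi_s / n_s, where n_s counts the frames
## assigned to s; frames in trimmed states are dropped (with a message).
weighted_cv_frames <- function(cvs, states, msm) {
  cv_list <- if (inherits(cvs, "cv_trajset")) cvs$trajectories else cvs
  if (!is.list(states)) states <- list(states)
  stopifnot(length(cv_list) == length(states))
  all_cv <- do.call(rbind, lapply(cv_list, function(m) m[, c(1, 2), drop = FALSE]))
  all_s <- unlist(states, use.names = FALSE)
  if (nrow(all_cv) != length(all_s))
    stop_memsm("state sequences and CV series are not frame-aligned")
  n_s <- tabulate(all_s, nbins = max(all_s, msm$active))
  w <- rep(0, length(all_s))
  keep <- all_s %in% msm$active
  if (any(!keep)) message(sprintf("%d frame(s) in trimmed states carry no weight", sum(!keep)))
  pi_full <- setNames(rep(0, length(n_s)), seq_along(n_s))
  pi_full[msm$active] <- msm$pi
  w[keep] <- pi_full[all_s[keep]] / n_s[all_s[keep]]
  cbind(all_cv[keep, , drop = FALSE], w = w[keep] / sum(w[keep]))
}

#' MSM-reweighted free-energy landscape over (depth, angle)
#'
#' Bins the frames on a 2-D grid, weighting each frame by the stationary
#' probability of its MSM state divided by the state's frame count, and
#' converts the normalized probability mass to free energy
#' `F = -kT log p`, shifted so the minimum is 0. Empty bins carry `NA`.
#'
#' @param cvs `cv_trajset` or list of per-trajectory CV matrices (first two
#'   columns d, theta).
#' @param states list of state sequences, frame-aligned with `cvs`.
#' @param msm an `msm_model` (pass `NULL` for a raw unweighted histogram).
#' @param bins either `c(n_d, n_theta)` (grid over the sampled range padded
#'   5%) or a list with numeric `d` and `theta` bin edges; default 40 x 40.
#' @param kT thermal energy, kcal/mol.
#' @return object of class `fel` (free-energy landscape): `d_edges`,
#'   `theta_edges`, `p` (probability mass per bin, `NA` where empty), `F`
#'   (kcal/mol), `kT`.
#' @export
msm_weighted_histogram <- function(cvs, states, msm, bins = c(40, 40),
                                   kT = 0.5961) {
  cv_list <- if (inherits(cvs, "cv_trajset")) cvs$trajectories else cvs
  if (is.null(msm)) {
    all_cv <- do.call(rbind, lapply(cv_list, function(m) m[, c(1, 2), drop = FALSE]))
    wf <- cbind(all_cv, w = rep(1 / nrow(all_cv), nrow(all_cv)))
  } else {
    wf <- weighted_cv_frames(cvs, states, msm)
  }
  if (!nrow(wf)) stop_memsm("no frames to histogram")
  if (is.list(bins)) {
    d_edges <- bins$d; t_edges <- bins$theta
  } else {
    pad <- function(r) r + c(-1, 1) * 0.05 * diff(r)
    rd <- pad(range(wf[, 1])); rt <- pad(range(wf[, 2]))
    d_edges <- seq(rd[1], rd[2], length.out = bins[1] + 1)
    t_edges <- seq(rt[1], rt[2], length.out = bins[2] + 1)
  }
  bi <- findInterval(wf[, 1], d_edges, rightmost.closed = TRUE)
  bj <- findInterval(wf[, 2], t_edges, rightmost.closed = TRUE)
  ok <- bi >= 1 & bi <= length(d_edges) - 1 & bj >= 1 & bj <= length(t_edges) - 1
  p <- matrix(0, length(d_edges) - 1, length(t_edges) - 1)
  tot <- tapply(wf[ok, 3], list(factor(bi[ok], seq_len(nrow(p))),
                                factor(bj[ok], seq_len(ncol(p)))), sum)
  tot[is.na(tot)] <- 0
  p[] <- tot
  p <- p / sum(p)
  Fm <- -kT * log(p)
  Fm[!is.finite(Fm)] <- NA
  Fm <- Fm - min(Fm, na.rm = TRUE)
  p[p == 0] <- NA
  structure(list(d_edges = d_edges, theta_edges = t_edges, p = p, F = Fm,
                 kT = kT), class = "fel")
}

#' Write a landscape as a CSV grid
#'
#' Columns: `d_center`, `theta_center`, `p`, `F_kcal_mol` (empty bins have
#' empty `p`/`F`).
#' @param fel an `fel` object.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(fel, path) {
  dc <- (head(fel$d_edges, -1) + tail(fel$d_edges, -1)) / 2
  tc <- (head(fel$theta_edges, -1) + tail(fel$theta_edges, -1)) / 2
  df <- data.frame(d_center = rep(dc, times = length(tc)),
                   theta_center = rep(tc, each = length(dc)),
                   p = as.numeric(fel$p), F_kcal_mol = as.numeric(fel$F))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a free-energy landscape
#' @param x an `fel` object.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @export
plot.fel <- function(x, ...) {
  graphics::image(x = (head(x$d_edges, -1) + tail(x$d_edges, -1)) / 2,
                  y = (head(x$theta_edges, -1) + tail(x$theta_edges, -1)) / 2,
                  z = x$F, xlab = "depth d (nm)", ylab = "angle (deg)",
                  col = grDevices::hcl.colors(50, "viridis", rev = TRUE), ...)
  invisible(x)
}

#' Local minima of a landscape
#'
#' Occupied bins whose free energy does not exceed any occupied bin within a
#' square neighborhood of `radius` bins and lies below
#' `min(F) + depth_cutoff`; adjacent qualifying bins are merged into one
#' minimum.
#'
#' @param fel an `fel` object.
#' @param depth_cutoff kcal/mol above the global minimum; default 2.
#' @param radius neighborhood radius in bins; default 2.
#' @return data frame with `d`, `theta`, `F` per minimum, ordered by `F`.
#' @export
find_local_minima <- function(fel, depth_cutoff = 2, radius = 2L) {
  Fm <- fel$F
  nr <- nrow(Fm); nc <- ncol(Fm)
  cand <- which(!is.na(Fm) & Fm <= depth_cutoff, arr.ind = TRUE)
  is_min <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    wnd <- Fm[max(1, i - radius):min(nr, i + radius),
              max(1, j - radius):min(nc, j + radius)]
    is_min[r] <- Fm[i, j] <= min(wnd, na.rm = TRUE) + 1e-12
  }
  cand <- cand[is_min, , drop = FALSE]
  if (!nrow(cand)) return(data.frame(d = numeric(), theta = numeric(), F = numeric()))
  ## merge contiguous qualifying bins (within `radius` of each other)
  grp <- seq_len(nrow(cand))
  repeat {
    changed <- FALSE
    for (a in seq_len(nrow(cand))) for (b in seq_len(nrow(cand))) {
      if (grp[a] != grp[b] &&
          abs(cand[a, 1] - cand[b, 1]) <= radius &&
          abs(cand[a, 2] - cand[b, 2]) <= radius) {
        grp[grp == grp[b]] <- grp[a]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  dc <- (head(fel$d_edges, -1) + tail(fel$d_edges, -1)) / 2
  tc <- (head(fel$theta_edges, -1) + tail(fel$theta_edges, -1)) / 2
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    rows <- which(grp == g)
    best <- rows[which.min(Fm[cand[rows, , drop = FALSE]])]
    data.frame(d = dc[cand[best, 1]], theta = tc[cand[best, 2]],
               F = Fm[cand[best, 1], cand[best, 2]])
  }))
  out[order(out$F), , drop = FALSE]
}

#' Propose deep/shallow basin rectangles from a landscape
#'
#' Takes the two lowest local minima and splits the plane at the midpoint of
#' their depth coordinates: the basin at smaller d is "deep", the other
#' "shallow"; each rectangle spans the landscape's angle range.
#'
#' @param fel an `fel` object.
#' @param depth_cutoff,radius passed to [find_local_minima()].
#' @return a [basin_definition()].
#' @export
propose_basins <- function(fel, depth_cutoff = 2, radius = 2L) {
  mins <- find_local_minima(fel, depth_cutoff, radius)
  if (nrow(mins) < 2)
    stop_memsm("found %d local minima; need 2 to propose basins", nrow(mins))
  mins <- mins[1:2, ]
  mins <- mins[order(mins$d), ]
  mid <- mean(mins$d)
  tr <- range(fel$theta_edges)
  basin_definition(
    deep = list(d = c(min(fel$d_edges), mid), theta = tr),
    shallow = list(d = c(mid, max(fel$d_edges)), theta = tr))
}

#' Basin free-energy difference from MSM-weighted frames
#'
#' `dG = -kT log(P_shallow / P_deep)` with basin probabilities summed from
#' the per-frame MSM weights; positive when the shallow basin is less
#' populated.
#'
#' @param cvs,states,msm as in [msm_weighted_histogram()].
#' @param basins a [basin_definition()].
#' @param kT kcal/mol.
#' @return list of class `deltag_result`: `P_deep`, `P_shallow`, `delta_g`,
#'   `kT`, `basins`.
#' @export
basin_deltaG <- function(cvs, states, msm, basins, kT = 0.5961) {
  wf <- weighted_cv_frames(cvs, states, msm)
  Pd <- sum(wf[in_basin(wf, basins$deep), 3])
  Ps <- sum(wf[in_basin(wf, basins$shallow), 3])
  if (Pd == 0 || Ps == 0)
    stop_memsm("zero-mass basin (P_deep = %g, P_shallow = %g); widen the basins", Pd, Ps)
  structure(list(P_deep = Pd, P_shallow = Ps,
                 delta_g = -kT * log(Ps / Pd), kT = kT, basins = basins),
            class = "deltag_result")
}

#' Bootstrap confidence interval for the basin free-energy difference
#'
#' Resamples trajectories (not frames, to respect autocorrelation) with
#' replacement B times; each replicate re-estimates the reversible MSM from
#' the resampled transition counts (tICA/clustering held fixed) and
#' recomputes `dG`; the percentile interval at `level` is reported.
#' Replicates in which a basin has zero mass are dropped and counted; more
#' than 20% dropped is an error.
#'
#' @param cvs `cv_trajset` or list of per-trajectory CV matrices.
#' @param states list of per-trajectory state sequences.
#' @param basins a [basin_definition()].
#' @param tau MSM lag, ns.
#' @param frame_interval ns between frames.
#' @param k number of cluster states.
#' @param B bootstrap replicates; default 200.
#' @param level CI level; default 0.95.
#' @param seed integer seed.
#' @param kT kcal/mol.
#' @return `deltag_result` with additional fields `ci` (lower, upper),
#'   `ci_range`, `level`, `B`, `n_dropped`, `seed`, `replicates`.
#' @export
bootstrap_deltaG <- function(cvs, states, basins, tau = 4.5, frame_interval,
                             k = NULL, B = 200L, level = 0.95, seed = 1L,
                             kT = 0.5961) {
  cv_list <- if (inherits(cvs, "cv_trajset")) cvs$trajectories else cvs
  if (length(cv_list) < 2) stop_memsm("need >= 2 trajectories to bootstrap")
  if (B < 1) stop_memsm("B must be >= 1")
  if (level <= 0 || level >= 1) stop_memsm("level must be in (0, 1)")
  k <- k %||% max(unlist(states))
  nt <- length(cv_list)

  ## Per-trajectory sufficient statistics: transition counts, frames per
  ## state, and basin frames per state. Every replicate then only needs a
  ## reversible MSM refit on summed counts.
  lf <- floor(tau / frame_interval + 1e-9)
  per <- lapply(seq_len(nt), function(i) {
    s <- states[[i]]
    cv <- cv_list[[i]][, c(1, 2), drop = FALSE]
    C <- if (length(s) > lf) {
      a <- s[1:(length(s) - lf)]; b <- s[(lf + 1):length(s)]
      matrix(tabulate((a - 1L) * k + b, k * k), k, k, byrow = TRUE)
    } else matrix(0, k, k)
    list(C = C,
         n_s = tabulate(s, k),
         deep_s = tabulate(s[in_basin(cv, basins$deep)], k),
         shal_s = tabulate(s[in_basin(cv, basins$shallow)], k))
  })

  dg_from <- function(idx) {
    C <- Reduce(`+`, lapply(per[idx], `[[`, "C"))
    n_s <- Reduce(`+`, lapply(per[idx], `[[`, "n_s"))
    dp <- Reduce(`+`, lapply(per[idx], `[[`, "deep_s"))
    sh <- Reduce(`+`, lapply(per[idx], `[[`, "shal_s"))
    active <- largest_connected_set(C)
    msm <- fit_reversible_msm(C[active, active, drop = FALSE], tau, active = active)
    w_s <- msm$pi / n_s[active]
    Pd <- sum(w_s * dp[active]); Ps <- sum(w_s * sh[active])
    if (Pd == 0 || Ps == 0) return(NULL)
    -kT * log(Ps / Pd)
  }

  point <- suppressMessages(dg_from(seq_len(nt)))
  if (is.null(point))
    stop_memsm("zero-mass basin in the full dataset; widen the basins")

  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(nt, nt, replace = TRUE)
      r <- tryCatch(suppressMessages(dg_from(idx)), error = function(e) NULL)
      if (is.null(r)) NA_real_ else r
    }, 0)
  })
  n_dropped <- sum(is.na(reps))
  if (n_dropped > 0.2 * B)
    stop_memsm("%d of %d bootstrap replicates had a zero-mass basin", n_dropped, B)
  good <- reps[!is.na(reps)]
  alpha <- (1 - level) / 2
  ## percentile interval with the (B+1)*alpha order-statistic convention of
  ## the classic bootstrap literature (quantile type 6)
  ci <- unname(quantile(good, c(alpha, 1 - alpha), type = 6))
  structure(list(P_deep = NA_real_, P_shallow = NA_real_, delta_g = point,
                 ci = ci, ci_range = diff(ci), level = level, B = as.integer(B),
                 n_dropped = n_dropped, seed = as.integer(seed), kT = kT,
                 basins = basins, replicates = good),
            class = "deltag_result")
}

#' Difference of basin free-energy differences
#'
#' `ddG = dG_b - dG_a`, both in kcal/mol at the same temperature.
#'
#' @param result_a,result_b `deltag_result` objects.
#' @return numeric, kcal/mol.
#' @export
delta_delta_G <- function(result_a, result_b) {
  if (!isTRUE(all.equal(result_a$kT, result_b$kT)))
    stop_memsm("results were computed at different kT")
  result_b$delta_g - result_a$delta_g
}

#' Waters coordinating a set of target atoms
#'
#' Per frame, the number of water oxygens within `d_max` (minimum image) of
#' any of the target atoms — a distance-contact proxy for coordinating
#' waters.
#'
#' @param traj,topo trajectory and topology.
#' @param target_atom_ids integer atom indices (rows of the topology).
#' @param d_max contact cutoff, nm; default 0.35.
#' @return integer vector, one count per frame.
#' @export
count_coordinating_waters <- function(traj, topo, target_atom_ids, d_max = 0.35) {
  if (!length(target_atom_ids) || any(target_atom_ids > nrow(topo)))
    stop_memsm("invalid target atom indices")
  wo <- role_idx(topo, "water_oxygen")
  vapply(seq_len(n_frames(traj)), function(f) {
    if (!length(wo)) return(0L)
    x <- frame_coords(traj, f)
    dm <- pairwise_dist_box(x[wo, , drop = FALSE],
                            x[target_atom_ids, , drop = FALSE], traj$box)
    sum(apply(dm, 1, min) <= d_max)
  }, 0L)
}

#' Export a basin free-energy result as JSON
#' @param result a `deltag_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_deltag_json <- function(result, path) {
  out <- result[c("delta_g", "P_deep", "P_shallow", "kT")]
  out$ci <- unname(result$ci)
  out$ci_range <- result$ci_range
  out$level <- result$level
  out$B <- result$B
  out$seed <- result$seed
  out$basins <- lapply(result$basins[c("deep", "shallow")],
                       function(b) list(d = b$d, theta = b$theta))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
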