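## Featurization: seven base featurizers over protein, water and lipid
## degrees of freedom, combined so that each featurization uses 0 or 1
## choice per subsystem (never all three absent), giving 35 combinations.

PROTEIN_CHOICES <- c("none", "dihedrals", "rmsd", "reciprocal_distances")
WATER_CHOICES <- c("none", "shell_0.3nm", "shell_1.0nm")
LIPID_CHOICES <- c("none", "lipid_shell", "lipid_weighted_distance")

#' Specify one combined featurization
#'
#' @param protein one of `"none"`, `"dihedrals"`, `"rmsd"`,
#'   `"reciprocal_distances"`.
#' @param water one of `"none"`, `"shell_0.3nm"`, `"shell_1.0nm"`.
#' @param lipid one of `"none"`, `"lipid_shell"`,
#'   `"lipid_weighted_distance"`.
#' @return object of class `feature_spec` with an `id` string.
#' @export
feature_spec <- function(protein = "none", water = "none", lipid = "none") {
  protein <- match.arg(protein, PROTEIN_CHOICES)
  water <- match.arg(water, WATER_CHOICES)
  lipid <- match.arg(lipid, LIPID_CHOICES)
  if (protein == "none" && water == "none" && lipid == "none")
    stop_memsm("a feature_spec must select at least one featurizer")
  structure(list(protein = protein, water = water, lipid = lipid,
                 id = paste(protein, water, lipid, sep = "+")),
            class = "feature_spec")
}

#' Enumerate all combined featurizations
#'
#' All combinations of one-or-none protein, water and lipid featurizer
#' (4 x 3 x 3 minus the empty combination = 35), in a fixed deterministic
#' order (protein fastest).
#'
#' @return list of 35 [feature_spec()] objects.
#' @export
enumerate_combined_featurizations <- function() {
  g <- expand.grid(protein = PROTEIN_CHOICES, water = WATER_CHOICES,
                   lipid = LIPID_CHOICES, stringsAsFactors = FALSE)
  g <- g[!(g$protein == "none" & g$water == "none" & g$lipid == "none"), ]
  lapply(seq_len(nrow(g)), function(i)
    feature_spec(g$protein[i], g$water[i], g$lipid[i]))
}

feature_matrix <- function(values, labels, frame_interval, spec_id = NA_character_) {
  colnames(values) <- labels
  attr(values, "frame_interval") <- frame_interval
  attr(values, "spec_id") <- spec_id
  values
}

## ---- dihedrals -------------------------------------------------------------

## Torsion angle (radians, IUPAC sign) for four atom positions given as
## frames x 3 matrices; vectorized over frames.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  m1 <- cross(n1, b2n)
  ## IUPAC sign convention (matches bio3d::torsion.xyz)
  -atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Backbone dihedral features
#'
#' phi/psi torsions of the peptide backbone, each encoded as a (sin, cos)
#' pair so the representation has no angular wrap discontinuity. Dihedrals
#' spanning a chain break (non-consecutive residue numbers, or residues with
#' missing N/CA/C) are omitted with a message.
#'
#' @param traj a [mem_trajectory()].
#' @param topo a [mem_topology()].
#' @return feature matrix, frames x (2 * n_dihedrals).
#' @export
backbone_dihedrals <- function(traj, topo) {
  bb <- topo$role %in% c("backbone", "alpha_carbon")
  key <- function(resno, elety) which(bb & topo$resno == resno & topo$elety == elety)
  res <- sort(unique(topo$resno[bb]))
  has <- vapply(res, function(r)
    length(key(r, "N")) == 1 && length(key(r, "CA")) == 1 && length(key(r, "C")) == 1,
    TRUE)
  if (any(!has)) message(sprintf("%d residue(s) lack complete N/CA/C backbones; their dihedrals are omitted", sum(!has)))
  res <- res[has]

  at <- function(r, e) { # frames x 3 coordinates of one named atom
    m <- traj$xyz[, key(r, e), , drop = FALSE]
    dim(m) <- c(dim(traj$xyz)[1], 3)
    m
  }
  cols <- list(); labels <- character()
  for (i in seq_along(res)) {
    r <- res[i]
    if (i > 1 && res[i - 1] == r - 1) { # phi: C(i-1), N(i), CA(i), C(i)
      a <- dihedral_angle(at(r - 1, "C"), at(r, "N"), at(r, "CA"), at(r, "C"))
      cols <- c(cols, list(sin(a), cos(a)))
      labels <- c(labels, paste0("phi_", r, c("_sin", "_cos")))
    }
    if (i < length(res) && res[i + 1] == r + 1) { # psi: N(i), CA(i), C(i), N(i+1)
      a <- dihedral_angle(at(r, "N"), at(r, "CA"), at(r, "C"), at(r + 1, "N"))
      cols <- c(cols, list(sin(a), cos(a)))
      labels <- c(labels, paste0("psi_", r, c("_sin", "_cos")))
    }
  }
  if (!length(cols)) stop_memsm("no complete backbone dihedrals in topology")
  feature_matrix(do.call(cbind, cols), labels, traj$frame_interval)
}

## ---- rmsd ------------------------------------------------------------------

#' RMSD to a reference structure
#'
#' Optimal-superposition (Kabsch) root-mean-square deviation of the protein
#' heavy atoms from a reference frame, in nm; one feature column.
#'
#' @param traj a [mem_trajectory()].
#' @param topo a [mem_topology()].
#' @param reference_coords atoms x 3 reference coordinates (nm), same atom
#'   set and order as the trajectory.
#' @return feature matrix, frames x 1.
#' @export
rmsd_to_reference <- function(traj, topo, reference_coords) {
  idx <- protein_heavy_idx(topo)
  if (length(idx) < 3) stop_memsm("need >= 3 protein heavy atoms for superposition")
  ref <- reference_coords[idx, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    kabsch_rmsd(ref, frame_coords(traj, f)[idx, , drop = FALSE]), 0)
  feature_matrix(matrix(vals, ncol = 1), "rmsd_nm", traj$frame_interval)
}

## Minimized RMSD between two centered point sets: Kabsch SVD rotation,
## then the explicit residual (numerically stabler than the trace formula,
## which loses ~8 digits to cancellation near zero).
kabsch_rmsd <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); b <- sweep(b, 2, colMeans(b))
  s <- svd(crossprod(a, b))
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% (t(s$u) * c(1, 1, d))
  sqrt(mean(rowSums((b %*% R - a)^2)))
}

## ---- reciprocal distances --------------------------------------------------

#' Histogram of reciprocal interatomic distances
#'
#' Per frame, the normalized histogram (summing to 1) of 1/d over all
#' unordered pairs of protein and ligand heavy atoms. Reciprocals beyond the
#' last bin edge are accumulated into the last bin.
#'
#' @param traj,topo trajectory and topology.
#' @param bin_edges increasing bin edges in nm^-1; default 50 bins on
#'   [0, 10].
#' @return feature matrix, frames x (length(bin_edges) - 1).
#' @export
reciprocal_distance_histogram <- function(traj, topo,
                                          bin_edges = seq(0, 10, length.out = 51)) {
  idx <- protein_heavy_idx(topo, include_ligand = TRUE)
  if (length(idx) < 2) stop_memsm("need >= 2 protein+ligand heavy atoms")
  nb <- length(bin_edges) - 1
  vals <- t(vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)[idx, , drop = FALSE]
    d <- stats::dist(x)
    if (any(d < 1e-6)) stop_memsm("coincident atoms (d < 1e-6 nm) in frame %d", f)
    r <- pmin(1 / as.numeric(d), bin_edges[nb + 1])
    h <- tabulate(pmin(findInterval(r, bin_edges, rightmost.closed = TRUE), nb), nb)
    h / sum(h)
  }, numeric(nb)))
  feature_matrix(vals, sprintf("invd_bin%02d", seq_len(nb)), traj$frame_interval)
}

## ---- solvent shells --------------------------------------------------------

#' Solvent-shell occupancy counts
#'
#' For every protein and ligand heavy atom, the number of solvent atoms
#' (water oxygens or lipid phosphorus markers) within `radius_nm`, under the
#' minimum-image convention of the orthorhombic box — a local instantaneous
#' solvent density probe.
#'
#' @param traj,topo trajectory and topology.
#' @param solvent_role `"water_oxygen"` or `"lipid_phosphorus"`.
#' @param radius_nm shell radius; must not exceed half the smallest box
#'   length (minimum image validity).
#' @return feature matrix, frames x n_heavy_atoms.
#' @export
solvent_shell_counts <- function(traj, topo, solvent_role, radius_nm) {
  stopifnot(solvent_role %in% c("water_oxygen", "lipid_phosphorus"))
  if (radius_nm <= 0) stop_memsm("radius must be > 0")
  if (radius_nm > min(traj$box) / 2)
    stop_memsm("radius %.2f nm exceeds half the smallest box length (%.2f nm)",
               radius_nm, min(traj$box) / 2)
  hv <- protein_heavy_idx(topo, include_ligand = TRUE)
  sv <- role_idx(topo, solvent_role)
  vals <- t(vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    if (!length(sv)) return(numeric(length(hv)))
    dm <- pairwise_dist_box(x[hv, , drop = FALSE], x[sv, , drop = FALSE], traj$box)
    rowSums(dm <= radius_nm)
  }, numeric(length(hv))))
  if (length(hv) == 1) vals <- matrix(vals, ncol = 1)
  labels <- sprintf("shell%g_%s%d_%s", radius_nm, topo$resid[hv],
                    topo$resno[hv], topo$elety[hv])
  feature_matrix(vals, labels, traj$frame_interval)
}

#' Smooth lipid-proximity features
#'
#' For every protein heavy atom, `sum_j exp(-d_ij / sigma)` over all lipid
#' phosphorus atoms (minimum-image distances) — a bounded, smooth weight that
#' grows with proximity to the phosphate plane.
#'
#' @param traj,topo trajectory and topology.
#' @param sigma_nm decay length of the exponential weight; default 0.3 nm.
#' @return feature matrix, frames x n_protein_heavy_atoms.
#' @export
lipid_weighted_distance <- function(traj, topo, sigma_nm = 0.3) {
  hv <- protein_heavy_idx(topo)
  lp <- role_idx(topo, "lipid_phosphorus")
  if (!length(lp)) stop_memsm("topology contains no lipid phosphorus atoms")
  vals <- t(vapply(seq_len(n_frames(traj)), function(f) {
    x <- frame_coords(traj, f)
    dm <- pairwise_dist_box(x[hv, , drop = FALSE], x[lp, , drop = FALSE], traj$box)
    rowSums(exp(-dm / sigma_nm))
  }, numeric(length(hv))))
  if (length(hv) == 1) vals <- matrix(vals, ncol = 1)
  labels <- sprintf("lipw_%s%d_%s", topo$resid[hv], topo$resno[hv], topo$elety[hv])
  feature_matrix(vals, labels, traj$frame_interval)
}

## ---- assembly --------------------------------------------------------------

#' Assemble a combined featurization
#'
#' Column-concatenates the featurizers selected by `spec`, preserving labels.
#'
#' @param traj,topo trajectory and topology.
#' @param spec a [feature_spec()].
#' @param params optional list: `reference_coords` (for the RMSD featurizer;
#'   defaults to the trajectory's first frame), `bin_edges`
#'   (reciprocal-distance histogram), `lipid_shell_radius` (nm, default 1.0),
#'   `lipid_sigma` (nm, default 0.3).
#' @return feature matrix, frames x n_features.
#' @export
assemble_features <- function(traj, topo, spec, params = list()) {
  stopifnot(inherits(spec, "feature_spec"))
  parts <- list()
  if (spec$protein == "dihedrals") parts <- c(parts, list(backbone_dihedrals(traj, topo)))
  if (spec$protein == "rmsd") {
    ref <- params$reference_coords %||% frame_coords(traj, 1)
    parts <- c(parts, list(rmsd_to_reference(traj, topo, ref)))
  }
  if (spec$protein == "reciprocal_distances") {
    be <- params$bin_edges %||% seq(0, 10, length.out = 51)
    parts <- c(parts, list(reciprocal_distance_histogram(traj, topo, be)))
  }
  if (spec$water == "shell_0.3nm")
    parts <- c(parts, list(solvent_shell_counts(traj, topo, "water_oxygen", 0.3)))
  if (spec$water == "shell_1.0nm")
    parts <- c(parts, list(solvent_shell_counts(traj, topo, "water_oxygen", 1.0)))
  if (spec$lipid == "lipid_shell") {
    r <- params$lipid_shell_radius %||% 1.0
    parts <- c(parts, list(solvent_shell_counts(traj, topo, "lipid_phosphorus", r)))
  }
  if (spec$lipid == "lipid_weighted_distance") {
    s <- params$lipid_sigma %||% 0.3
    parts <- c(parts, list(lipid_weighted_distance(traj, topo, s)))
  }
  vals <- do.call(cbind, parts)
  check_finite(vals, sprintf("features of spec %s", spec$id))
  feature_matrix(vals, colnames(vals), traj$frame_interval, spec$id)
}

#' Featurize a whole dataset consistently
#'
#' Applies [assemble_features()] to every trajectory with shared parameters
#' (in particular one common RMSD reference, taken from the first frame of
#' the first trajectory when not supplied).
#'
#' @param trajectories list of [mem_trajectory()].
#' @param topo shared topology.
#' @param spec a [feature_spec()].
#' @param params see [assemble_features()].
#' @return list of feature matrices, one per trajectory.
#' @export
featurize_dataset <- function(trajectories, topo, spec, params = list()) {
  if (is.null(params$reference_coords) && spec$protein == "rmsd")
    params$reference_coords <- frame_coords(trajectories[[1]], 1)
  lapply(trajectories, assemble_features, topo = topo, spec = spec, params = params)
}
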