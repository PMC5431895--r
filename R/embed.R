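## Embedding of (depth, angle) ground truth as toy atomistic systems.
##
## Each (d, theta) frame is realized as a rigid-body placement of a
## pseudo-atomistic peptide template in a slab "membrane": lipid phosphorus
## markers on jittered lattices at the two leaflet planes, and water oxygens
## whose number density is bulk-like outside the headgroup region, decays
## linearly through it, and vanishes in the hydrocarbon core. The embedding
## places the peptide relative to the *realized* phosphorus planes of the
## frame, so recomputing the collective variables from the coordinates
## reproduces the input (d, theta) to floating-point accuracy.

#' Default pseudo-atomistic peptide template
#'
#' A 50-residue rigid body in its own frame: backbone N/CA/C for every
#' residue on an idealized helical path, CB pseudo-sidechain atoms on a
#' subset of residues, a structural zinc near the C31/C34/H1/C50 layer, and a
#' ring of ligand heavy atoms at the binding site. The body frame is chosen
#' so the binding-site centroid (mean CA of M9, T12, L21, V25) sits at the
#' origin and the distal centroid (mean of CA F3, G35, N48 and the zinc)
#' lies on the +z axis, which makes the rigid placement in
#' [embed_frames()] exact by construction.
#'
#' @return list with `topology` ([mem_topology()]) and `coords` (atoms x 3
#'   nm, body frame).
#' @export
default_peptide_template <- function() {
  n_res <- 50L
  resname <- rep("ALA", n_res)
  named <- c("1" = "HIS", "3" = "PHE", "9" = "MET", "12" = "THR",
             "21" = "LEU", "25" = "VAL", "31" = "CYS", "34" = "CYS",
             "35" = "GLY", "48" = "ASN", "50" = "CYS")
  resname[as.integer(names(named))] <- named

  rise <- 0.05; radius <- 0.45; twist <- 100 * pi / 180
  ca <- cbind(radius * cos(twist * seq_len(n_res)),
              radius * sin(twist * seq_len(n_res)),
              rise * seq_len(n_res))
  ## N and C flank each CA, rotating with the helix so that consecutive
  ## C(i-1)-N(i)-CA(i)-C(i) atoms are never collinear.
  ang <- twist * seq_len(n_res)
  off_n <- cbind(-0.10 * cos(ang + 0.6), -0.10 * sin(ang + 0.6), -0.12)
  off_c <- cbind(0.10 * cos(ang - 0.6), 0.10 * sin(ang - 0.6), 0.12)
  has_cb <- seq_len(n_res) %in% c(3L, 9L, 12L, 21L, 25L, 48L)
  off_cb <- cbind(0.15 * cos(ang + pi), 0.15 * sin(ang + pi), 0)

  rows <- list(); coords <- list()
  for (i in seq_len(n_res)) {
    rows[[length(rows) + 1L]] <- data.frame(
      elety = c("N", "CA", "C", if (has_cb[i]) "CB"),
      resid = resname[i], resno = i,
      role = c("backbone", "alpha_carbon", "backbone",
               if (has_cb[i]) "protein_heavy"),
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <-
      rbind(ca[i, ] + off_n[i, ], ca[i, ], ca[i, ] + off_c[i, ],
            if (has_cb[i]) ca[i, ] + off_cb[i, ])
  }
  ## Structural zinc near the coordinating layer (H1, C31, C34, C50).
  zn <- colMeans(ca[c(1L, 31L, 34L, 50L), ]) + c(0.1, 0.1, 0.05)
  rows[[length(rows) + 1L]] <- data.frame(elety = "ZN", resid = "ZN",
                                          resno = 51L, role = "zinc",
                                          stringsAsFactors = FALSE)
  coords[[length(coords) + 1L]] <- matrix(zn, 1)
  ## Ligand heavy atoms: a ring at the binding site.
  bind0 <- colMeans(ca[c(9L, 12L, 21L, 25L), ])
  phi <- 2 * pi * (0:7) / 8
  lig <- cbind(bind0[1] + 0.3 * cos(phi), bind0[2] + 0.3 * sin(phi),
               bind0[3] - 0.15)
  rows[[length(rows) + 1L]] <- data.frame(elety = paste0("C", 1:8),
                                          resid = "LIG", resno = 52L,
                                          role = "ligand_heavy",
                                          stringsAsFactors = FALSE)
  coords[[length(coords) + 1L]] <- lig

  atoms <- do.call(rbind, rows)
  atoms <- cbind(eleno = seq_len(nrow(atoms)), atoms)
  xyz <- do.call(rbind, coords)

  ## Body frame: binding centroid at the origin, distal centroid on +z.
  topo <- mem_topology(atoms)
  xyz <- sweep(xyz, 2, centroid_of(topo, xyz, "binding"))
  v <- centroid_of(topo, xyz, "distal")
  xyz <- xyz %*% t(rotation_to_z(v))
  list(topology = topo, coords = xyz)
}

## Centroids that define the insertion-depth / tilt geometry: the
## binding-site centroid averages the alpha carbons of M9, T12, L21 and V25;
## the distal centroid averages the alpha carbons of F3, G35, N48 and the
## zinc position.
centroid_of <- function(topo, coords, which = c("binding", "distal")) {
  which <- match.arg(which)
  if (which == "binding") {
    idx <- which(topo$role == "alpha_carbon" & topo$resno %in% c(9, 12, 21, 25))
    if (length(idx) != 4) stop_memsm("missing binding-site alpha carbons (M9, T12, L21, V25)")
  } else {
    ca <- which(topo$role == "alpha_carbon" & topo$resno %in% c(3, 35, 48))
    zn <- which(topo$role == "zinc")
    if (length(ca) != 3 || length(zn) != 1)
      stop_memsm("missing distal atoms (CA of F3, G35, N48 and the zinc)")
    idx <- c(ca, zn)
  }
  colMeans(coords[idx, , drop = FALSE])
}

## Rotation matrix taking unit(v) to +e_z (Rodrigues construction).
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  axis <- c(v[2] * z[3] - v[3] * z[2], v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2)); c0 <- sum(v * z)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    return(diag(c(1, -1, -1))) # v = -z: rotate pi about x
  }
  axis <- axis / s
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c0) * (K %*% K)
}

#' Configure the toy membrane embedding
#'
#' @param leaflet_z distance of each phosphorus plane from the membrane
#'   center, nm.
#' @param hydrocarbon_halfwidth half-width of the water-free hydrocarbon
#'   core, nm; must be < `leaflet_z`. Between the two, water density ramps
#'   linearly from zero to bulk (the partially hydrated headgroup region).
#' @param water_bulk_density bulk water-oxygen pseudo-atom density, nm^-3.
#' @param n_lipids_per_leaflet phosphorus markers per leaflet (a jittered
#'   square lattice).
#' @param lipid_jitter lateral and vertical lattice jitter standard
#'   deviations, nm (length 2).
#' @param peptide_template list with `topology` and `coords` as returned by
#'   [default_peptide_template()].
#' @param box orthorhombic box lengths, nm; the membrane center sits at
#'   `box[3]/2`.
#' @param seed integer seed for jitter, azimuths and water placement.
#' @return object of class `embed_config`.
#' @export
embed_config <- function(leaflet_z = 2.0, hydrocarbon_halfwidth = 1.4,
                         water_bulk_density = 6.0, n_lipids_per_leaflet = 64L,
                         lipid_jitter = c(0.08, 0.03),
                         peptide_template = default_peptide_template(),
                         box = c(5, 5, 10), seed = 1L) {
  if (hydrocarbon_halfwidth >= leaflet_z)
    stop_memsm("hydrocarbon_halfwidth must be < leaflet_z")
  stopifnot(length(box) == 3, all(box > 0), n_lipids_per_leaflet >= 1)
  structure(list(leaflet_z = leaflet_z,
                 hydrocarbon_halfwidth = hydrocarbon_halfwidth,
                 water_bulk_density = water_bulk_density,
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 lipid_jitter = lipid_jitter,
                 peptide_template = peptide_template,
                 box = as.numeric(box), seed = as.integer(seed)),
            class = "embed_config")
}

## Deterministic water counts per region (top/bottom bulk slabs and the two
## linear-ramp headgroup shells), from the configured bulk density.
water_counts <- function(embed) {
  A <- embed$box[1] * embed$box[2]
  zc <- embed$box[3] / 2
  h_bulk_top <- embed$box[3] - (zc + embed$leaflet_z)
  h_bulk_bot <- zc - embed$leaflet_z
  h_ramp <- embed$leaflet_z - embed$hydrocarbon_halfwidth
  rho <- embed$water_bulk_density
  c(bulk_top = round(rho * A * h_bulk_top),
    bulk_bot = round(rho * A * h_bulk_bot),
    ramp_top = round(rho * A * h_ramp / 2),
    ramp_bot = round(rho * A * h_ramp / 2))
}

#' Embed collective-variable trajectories as toy atomistic systems
#'
#' Realizes every (d, theta) frame as coordinates: the peptide template is
#' rigidly placed with its binding-site centroid at depth `d` above the
#' frame's realized membrane mid-plane and its body axis at angle `theta` to
#' the membrane plane (random azimuth); lipid phosphorus markers are jittered
#' lattices at +/- `leaflet_z`; water oxygens follow the z-graded density.
#' The peptide always sits on the upper leaflet side.
#'
#' @param cvs a `cv_trajset` from [sample_langevin()].
#' @param embed an [embed_config()].
#' @return list with `topology` (shared [mem_topology()]) and `trajectories`
#'   (list of [mem_trajectory()]).
#' @export
embed_frames <- function(cvs, embed) {
  stopifnot(inherits(cvs, "cv_trajset"), inherits(embed, "embed_config"))
  tpl <- embed$peptide_template
  n_pep <- nrow(tpl$topology)
  n_lip <- 2L * embed$n_lipids_per_leaflet
  wc <- water_counts(embed)
  n_wat <- sum(wc)

  lip_rows <- data.frame(eleno = n_pep + seq_len(n_lip), elety = "P",
                         resid = "LIP", resno = 100L + seq_len(n_lip),
                         role = "lipid_phosphorus", stringsAsFactors = FALSE)
  wat_rows <- data.frame(eleno = n_pep + n_lip + seq_len(n_wat), elety = "O",
                         resid = "HOH", resno = 1000L + seq_len(n_wat),
                         role = "water_oxygen", stringsAsFactors = FALSE)
  topo <- mem_topology(rbind(cbind(tpl$topology), lip_rows, wat_rows))

  zc_box <- embed$box[3] / 2
  side <- ceiling(sqrt(embed$n_lipids_per_leaflet))
  lat <- expand.grid(x = (seq_len(side) - 0.5) * embed$box[1] / side,
                     y = (seq_len(side) - 0.5) * embed$box[2] / side)
  lat <- as.matrix(lat[seq_len(embed$n_lipids_per_leaflet), ])
  lxy <- embed$lipid_jitter[1]; lz <- embed$lipid_jitter[2]
  hw <- embed$hydrocarbon_halfwidth; lf <- embed$leaflet_z
  ramp_h <- lf - hw

  max_ext <- max(abs(range(tpl$coords))) + 0.1

  trajectories <- with_seed(embed$seed, lapply(cvs$trajectories, function(m) {
    nf <- nrow(m)
    xyz <- array(NA_real_, c(nf, nrow(topo), 3))
    for (f in seq_len(nf)) {
      ## leaflets: jittered lattices; the realized means define the frame's
      ## membrane mid-plane used for the peptide placement below.
      top_p <- cbind(lat[, 1] + rnorm(nrow(lat), 0, lxy),
                     lat[, 2] + rnorm(nrow(lat), 0, lxy),
                     zc_box + lf + rnorm(nrow(lat), 0, lz))
      bot_p <- cbind(lat[, 1] + rnorm(nrow(lat), 0, lxy),
                     lat[, 2] + rnorm(nrow(lat), 0, lxy),
                     zc_box - lf + rnorm(nrow(lat), 0, lz))
      z_center <- (mean(top_p[, 3]) + mean(bot_p[, 3])) / 2

      d <- m[f, "d"]; th <- m[f, "theta"] * pi / 180
      phi <- runif(1, 0, 2 * pi)
      R <- rot_z(phi) %*% rot_y(pi / 2 - th)
      pep <- tpl$coords %*% t(R)
      pep <- sweep(pep, 2, c(embed$box[1] / 2, embed$box[2] / 2, z_center + d), "+")
      if (any(pep < 0) || any(sweep(pep, 2, embed$box) > 0))
        stop_memsm("peptide extends outside the box (extent %.2f nm); use a larger box", max_ext)

      wat <- rbind(
        cbind(runif(wc["bulk_top"], 0, embed$box[1]),
              runif(wc["bulk_top"], 0, embed$box[2]),
              runif(wc["bulk_top"], zc_box + lf, embed$box[3])),
        cbind(runif(wc["bulk_bot"], 0, embed$box[1]),
              runif(wc["bulk_bot"], 0, embed$box[2]),
              runif(wc["bulk_bot"], 0, zc_box - lf)),
        ## linear ramp: density ~ (|z - zc| - hw) / ramp_h, inverse CDF
        cbind(runif(wc["ramp_top"], 0, embed$box[1]),
              runif(wc["ramp_top"], 0, embed$box[2]),
              zc_box + hw + ramp_h * sqrt(runif(wc["ramp_top"]))),
        cbind(runif(wc["ramp_bot"], 0, embed$box[1]),
              runif(wc["ramp_bot"], 0, embed$box[2]),
              zc_box - hw - ramp_h * sqrt(runif(wc["ramp_bot"]))))

      xyz[f, , ] <- rbind(pep, top_p, bot_p, wat)
    }
    mem_trajectory(xyz, embed$box, cvs$frame_interval, topo)
  }))
  list(topology = topo, trajectories = trajectories)
}

rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                            3, 3, byrow = TRUE)
rot_y <- function(a) matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)),
                            3, 3, byrow = TRUE)
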