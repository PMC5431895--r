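## Topology and trajectory containers.
##
## A topology is a data frame of atoms with a mutually exclusive `role` label
## that every featurizer keys on; a trajectory is a frames x atoms x 3 array
## of coordinates in nm with an orthorhombic box and a frame interval in ns.

ATOM_ROLES <- c("protein_heavy", "backbone", "alpha_carbon", "ligand_heavy",
                "water_oxygen", "lipid_phosphorus", "zinc")

#' Construct a topology
#'
#' @param atoms data frame with columns `eleno` (atom serial), `elety` (atom
#'   name), `resid` (residue name), `resno` (residue number), `role` (one of
#'   `protein_heavy`, `backbone`, `alpha_carbon`, `ligand_heavy`,
#'   `water_oxygen`, `lipid_phosphorus`, `zinc`). Roles are mutually
#'   exclusive; "all protein heavy atoms" is the union of the first three.
#' @return object of class `mem_topology` (a data frame).
#' @export
mem_topology <- function(atoms) {
  need <- c("eleno", "elety", "resid", "resno", "role")
  if (!all(need %in% names(atoms)))
    stop_memsm("topology needs columns: %s", paste(need, collapse = ", "))
  bad <- setdiff(unique(atoms$role), ATOM_ROLES)
  if (length(bad)) stop_memsm("unknown atom role(s): %s", paste(bad, collapse = ", "))
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  class(atoms) <- c("mem_topology", "data.frame")
  atoms
}

#' Indices of all protein heavy atoms (sidechain + backbone + alpha carbons)
#' @param topo a [mem_topology()].
#' @param include_ligand also include ligand heavy atoms.
#' @return integer atom indices (row positions in the topology).
#' @export
protein_heavy_idx <- function(topo, include_ligand = FALSE) {
  roles <- c("protein_heavy", "backbone", "alpha_carbon",
             if (include_ligand) "ligand_heavy")
  which(topo$role %in% roles)
}

role_idx <- function(topo, role) which(topo$role == role)

#' Construct a trajectory
#'
#' @param xyz numeric array frames x atoms x 3, coordinates in nm.
#' @param box orthorhombic box lengths, nm (length 3).
#' @param frame_interval time between frames, ns.
#' @param topology optional [mem_topology()] used to validate the atom count.
#' @return object of class `mem_trajectory`.
#' @export
mem_trajectory <- function(xyz, box, frame_interval, topology = NULL) {
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3, length(box) == 3)
  if (frame_interval <= 0) stop_memsm("frame_interval must be > 0")
  if (!is.null(topology) && nrow(topology) != dim(xyz)[2])
    stop_memsm("trajectory has %d atoms but topology has %d rows",
               dim(xyz)[2], nrow(topology))
  structure(list(xyz = xyz, box = as.numeric(box),
                 frame_interval = frame_interval),
            class = "mem_trajectory")
}

n_frames <- function(traj) dim(traj$xyz)[1]

## Single frame as an atoms x 3 matrix.
frame_coords <- function(traj, i) {
  m <- traj$xyz[i, , , drop = FALSE]
  dim(m) <- dim(traj$xyz)[2:3]
  m
}

#' Write a topology (with one frame of coordinates) as PDB
#'
#' Roles are encoded in residue names: waters as `HOH` (oxygen only), lipid
#' phosphorus markers as `LIP`, the structural zinc as `ZN`, ligand heavy
#' atoms as `LIG`; peptide atoms keep their residue names and numbering.
#' Coordinates are converted from nm to Angstrom on output.
#'
#' @param topo a [mem_topology()].
#' @param coords atoms x 3 matrix in nm.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_topology_pdb <- function(topo, coords, path) {
  stopifnot(nrow(coords) == nrow(topo))
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)) * 10,
                   eleno = topo$eleno, elety = topo$elety,
                   resid = topo$resid, resno = topo$resno)
  invisible(path)
}

#' Read a topology from PDB
#'
#' Inverts the role encoding of [write_topology_pdb()]: `HOH` oxygen ->
#' `water_oxygen`, `LIP` -> `lipid_phosphorus`, `ZN` -> `zinc`, `LIG` ->
#' `ligand_heavy`; remaining (peptide) atoms are split into `alpha_carbon`
#' (CA), `backbone` (N, C) and `protein_heavy` (other heavy atoms); hydrogens
#' are dropped.
#'
#' @param path PDB file.
#' @return list with `topology` ([mem_topology()]) and `coords` (atoms x 3,
#'   nm).
#' @export
read_topology_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  keep <- !grepl("^H", trimws(a$elety)) # drop hydrogens
  a <- a[keep, , drop = FALSE]
  role <- ifelse(a$resid == "HOH", "water_oxygen",
          ifelse(a$resid == "LIP", "lipid_phosphorus",
          ifelse(a$resid == "ZN", "zinc",
          ifelse(a$resid == "LIG", "ligand_heavy",
          ifelse(a$elety == "CA", "alpha_carbon",
          ifelse(a$elety %in% c("N", "C"), "backbone", "protein_heavy"))))))
  topo <- mem_topology(data.frame(eleno = a$eleno, elety = a$elety,
                                  resid = a$resid, resno = a$resno,
                                  role = role, stringsAsFactors = FALSE))
  coords <- cbind(a$x, a$y, a$z) / 10
  list(topology = topo, coords = coords)
}

#' Read a DCD coordinate set as a trajectory
#'
#' Thin wrapper over [bio3d::read.dcd()]. DCD stores Angstrom; coordinates
#' are converted to nm. The frame interval and box are supplied by the
#' caller because DCD headers do not carry them reliably.
#'
#' @param path DCD file.
#' @param frame_interval ns between frames.
#' @param box orthorhombic box lengths in nm.
#' @return a [mem_trajectory()].
#' @export
read_trajectory_dcd <- function(path, frame_interval, box) {
  m <- bio3d::read.dcd(path, verbose = FALSE) # frames x (3*atoms), Angstrom
  nat <- ncol(m) / 3
  xyz <- array(NA_real_, c(nrow(m), nat, 3))
  for (k in 1:3) xyz[, , k] <- m[, seq(k, ncol(m), by = 3)] / 10
  mem_trajectory(xyz, box, frame_interval)
}

#' Write / read a trajectory as a plain-text array container
#'
#' Long-format CSV with columns `frame`, `atom`, `x`, `y`, `z` (nm) and
#' header comments carrying the box and frame interval — a documented,
#' text-only interchange format for the toy systems this package generates.
#'
#' @param traj a [mem_trajectory()].
#' @param path CSV path.
#' @return `path` invisibly, or the reconstructed [mem_trajectory()].
#' @export
write_traj_csv <- function(traj, path) {
  nf <- n_frames(traj); nat <- dim(traj$xyz)[2]
  df <- data.frame(frame = rep(seq_len(nf), times = nat),
                   atom = rep(seq_len(nat), each = nf),
                   x = as.numeric(traj$xyz[, , 1]),
                   y = as.numeric(traj$xyz[, , 2]),
                   z = as.numeric(traj$xyz[, , 3]))
  con <- file(path, "w")
  writeLines(c(sprintf("# box_nm: %.17g %.17g %.17g", traj$box[1], traj$box[2], traj$box[3]),
               sprintf("# frame_interval_ns: %.17g", traj$frame_interval)), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_traj_csv
#' @export
read_traj_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  box <- as.numeric(strsplit(trimws(sub("# box_nm:", "", hdr[1])), "\\s+")[[1]])
  fi <- as.numeric(sub("# frame_interval_ns:", "", hdr[2]))
  df <- read.csv(path, comment.char = "#")
  nf <- max(df$frame); nat <- max(df$atom)
  df <- df[order(df$atom, df$frame), ]
  xyz <- array(NA_real_, c(nf, nat, 3))
  xyz[, , 1] <- df$x; xyz[, , 2] <- df$y; xyz[, , 3] <- df$z
  mem_trajectory(xyz, box, fi)
}
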