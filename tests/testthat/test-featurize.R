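test_that("the combination scheme yields 35 distinct non-empty featurizations", {
  specs <- enumerate_combined_featurizations()
  expect_length(specs, 35)
  ids <- vapply(specs, function(s) s$id, "")
  expect_length(unique(ids), 35)
  expect_false("none+none+none" %in% ids)
  ## exactly one protein-only spec per protein featurizer
  solo <- vapply(specs, function(s) s$water == "none" && s$lipid == "none", TRUE)
  expect_equal(sum(solo), 3)
  expect_error(feature_spec("none", "none", "none"), "at least one")
})

test_that("backbone dihedrals match an independent evaluation and encode on the circle", {
  tpl <- default_peptide_template()
  nat <- nrow(tpl$topology)
  set.seed(8)
  xyz <- array(NA_real_, c(3, nat, 3))
  xyz[1, , ] <- tpl$coords
  for (f in 2:3) xyz[f, , ] <- tpl$coords %*% t(random_rotation()) +
    matrix(rnorm(3), nat, 3, byrow = TRUE)
  traj <- mem_trajectory(xyz, c(20, 20, 20), 1, tpl$topology)
  fm <- backbone_dihedrals(traj, tpl$topology)

  ## rigid motion leaves every dihedral feature unchanged
  expect_equal(fm[2, ], fm[1, ], tolerance = 1e-9)
  expect_equal(fm[3, ], fm[1, ], tolerance = 1e-9)

  ## sin^2 + cos^2 = 1 per angle per frame
  s2 <- fm[, grepl("_sin$", colnames(fm)), drop = FALSE]^2 +
    fm[, grepl("_cos$", colnames(fm)), drop = FALSE]^2
  expect_equal(as.numeric(s2), rep(1, length(s2)), tolerance = 1e-12)

  ## phi of residue 10 against the textbook cross-product oracle
  topo <- tpl$topology
  at <- function(r, e) tpl$coords[which(topo$resno == r & topo$elety == e), ]
  ang <- dihedral_oracle(at(9, "C"), at(10, "N"), at(10, "CA"), at(10, "C"))
  expect_equal(unname(fm[1, "phi_10_sin"]), sin(ang), tolerance = 1e-9)
  expect_equal(unname(fm[1, "phi_10_cos"]), cos(ang), tolerance = 1e-9)

  ## and against bio3d's torsion routine on hand-placed atoms (both signs)
  for (zs in c(0.12, -0.12)) {
    p <- rbind(c(0, 0, 0), c(0.15, 0, 0), c(0.2, 0.14, 0), c(0.3, 0.2, zs))
    own <- memsm:::dihedral_angle(matrix(p[1, ], 1), matrix(p[2, ], 1),
                                  matrix(p[3, ], 1), matrix(p[4, ], 1))
    b3d <- bio3d::torsion.xyz(as.numeric(t(p))) * pi / 180
    expect_equal(as.numeric(own), as.numeric(b3d), tolerance = 1e-6)
  }
})

test_that("dihedrals skip residues across chain breaks", {
  tpl <- default_peptide_template()
  keep <- !(tpl$topology$resno %in% 26L) # remove residue 26 entirely
  topo <- mem_topology(tpl$topology[keep, ])
  xyz <- array(tpl$coords[keep, ], c(1, sum(keep), 3))
  traj <- mem_trajectory(xyz, c(20, 20, 20), 1, topo)
  fm <- backbone_dihedrals(traj, topo)
  expect_false(any(grepl("^phi_26|^psi_26", colnames(fm))))
  expect_false(any(grepl("^phi_27_", colnames(fm)))) # needs C of residue 26
  expect_false(any(grepl("^psi_25_", colnames(fm)))) # needs N of residue 26
  expect_true(any(grepl("^phi_25_", colnames(fm))))
})

test_that("superposition RMSD is zero under rigid motion and matches a grid search", {
  tpl <- default_peptide_template()
  nat <- nrow(tpl$topology)
  set.seed(21)
  xyz <- array(NA_real_, c(3, nat, 3))
  xyz[1, , ] <- tpl$coords
  xyz[2, , ] <- tpl$coords %*% t(random_rotation()) + matrix(runif(3), nat, 3, byrow = TRUE)
  xyz[3, , ] <- tpl$coords + array(rnorm(nat * 3, 0, 0.05), c(nat, 3))
  traj <- mem_trajectory(xyz, c(20, 20, 20), 1, tpl$topology)
  fm <- rmsd_to_reference(traj, tpl$topology, tpl$coords)
  expect_equal(unname(fm[1, 1]), 0, tolerance = 1e-9)
  expect_equal(unname(fm[2, 1]), 0, tolerance = 1e-9)
  expect_gt(fm[3, 1], 0)

  ## 4-atom toy pair against the nested-grid rotation-search oracle
  a <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0, 0.25, 0), c(0.1, 0.1, 0.3))
  b <- a %*% t(random_rotation()) + array(rnorm(12, 0, 0.04), c(4, 3))
  expect_equal(memsm:::kabsch_rmsd(a, b), grid_rmsd_oracle(a, b), tolerance = 1e-4)
})

test_that("reciprocal-distance histograms normalize and match pair enumeration", {
  ## two atoms 0.5 nm apart: a single count in the bin containing 2 nm^-1
  two <- toy_system(c("protein_heavy", "protein_heavy"),
                    rbind(c(1, 1, 1), c(1, 1, 1.5)))
  fm <- reciprocal_distance_histogram(two$traj, two$topo)
  expect_equal(sum(fm[1, ]), 1)
  edges <- seq(0, 10, length.out = 51)
  expect_equal(unname(fm[1, findInterval(2, edges)]), 1)

  ## five atoms: histogram equals explicit enumeration of the 10 reciprocals
  set.seed(3)
  coords <- matrix(runif(15, 0, 2), 5, 3)
  five <- toy_system(rep("protein_heavy", 5), coords)
  fm5 <- reciprocal_distance_histogram(five$traj, five$topo)
  recip <- 1 / as.numeric(dist(coords))
  hand <- tabulate(findInterval(pmin(recip, 10), edges, rightmost.closed = TRUE), 50)
  expect_equal(as.numeric(fm5[1, ]), hand / 10, tolerance = 1e-12)

  co <- toy_system(rep("protein_heavy", 2), rbind(c(1, 1, 1), c(1, 1, 1 + 1e-9)))
  expect_error(reciprocal_distance_histogram(co$traj, co$topo), "coincident")
})

test_that("solvent-shell counts match a brute-force minimum-image loop", {
  ## no solvent: all-zero features
  dry <- toy_system(rep("protein_heavy", 3), matrix(runif(9, 0, 3), 3, 3))
  expect_true(all(solvent_shell_counts(dry$traj, dry$topo, "water_oxygen", 0.3) == 0))

  ## one water 0.25 nm from exactly one heavy atom at radius 0.3
  one <- toy_system(c("protein_heavy", "protein_heavy", "water_oxygen"),
                    rbind(c(1, 1, 1), c(3, 3, 3), c(1, 1, 1.25)))
  fm <- solvent_shell_counts(one$traj, one$topo, "water_oxygen", 0.3)
  expect_equal(as.numeric(fm[1, ]), c(1, 0))

  ## 50 random waters under periodic boundaries vs an O(N^2) double loop
  set.seed(12)
  box <- c(4, 4, 4)
  roles <- c(rep("protein_heavy", 8), rep("water_oxygen", 50))
  coords <- matrix(runif(58 * 3, 0, 4), 58, 3)
  sys <- toy_system(roles, coords, box = box)
  fm50 <- solvent_shell_counts(sys$traj, sys$topo, "water_oxygen", 1.0)
  brute <- sapply(1:8, function(i) {
    n <- 0
    for (j in 9:58) {
      dv <- abs(coords[i, ] - coords[j, ])
      dv <- pmin(dv, box - dv)
      if (sqrt(sum(dv^2)) <= 1.0) n <- n + 1
    }
    n
  })
  expect_equal(as.numeric(fm50[1, ]), brute)

  expect_error(solvent_shell_counts(sys$traj, sys$topo, "water_oxygen", 2.5),
               "half the smallest box")
})

test_that("lipid proximity weights follow the exponential form", {
  ## single phosphorus at distance sigma: feature = exp(-1)
  sys <- toy_system(c("protein_heavy", "lipid_phosphorus"),
                    rbind(c(1, 1, 1), c(1, 1, 1.3)))
  fm <- lipid_weighted_distance(sys$traj, sys$topo, sigma_nm = 0.3)
  expect_equal(as.numeric(fm[1, 1]), exp(-1), tolerance = 1e-12)

  ## far phosphorus contributes nearly nothing
  far <- toy_system(c("protein_heavy", "lipid_phosphorus"),
                    rbind(c(1, 1, 1), c(1, 1, 5)), box = c(30, 30, 30))
  expect_lt(lipid_weighted_distance(far$traj, far$topo, 0.3)[1, 1], 1e-5)

  ## 3 heavy atoms / 2 phosphorus against hand-summed exponentials
  set.seed(5)
  coords <- matrix(runif(15, 0, 2), 5, 3)
  sys2 <- toy_system(c(rep("protein_heavy", 3), rep("lipid_phosphorus", 2)),
                     coords, box = c(12, 12, 12))
  fm2 <- lipid_weighted_distance(sys2$traj, sys2$topo, 0.3)
  hand <- sapply(1:3, function(i)
    sum(exp(-sqrt(rowSums((coords[4:5, ] - matrix(coords[i, ], 2, 3, byrow = TRUE))^2)) / 0.3)))
  ## box is large relative to the coordinates, so minimum image is identity
  expect_equal(as.numeric(fm2[1, ]), hand, tolerance = 1e-12)
})

test_that("assembled features concatenate their parts deterministically", {
  cvs <- structure(list(trajectories = list(cbind(d = c(1.2, 1.4), theta = c(20, 30))),
                        frame_interval = 0.5, seed = 1L, config_hash = "x"),
                   class = "cv_trajset")
  emb <- embed_config(seed = 6, water_bulk_density = 2)
  sys <- embed_frames(cvs, emb)
  traj <- sys$trajectories[[1]]; topo <- sys$topology

  only_dih <- assemble_features(traj, topo, feature_spec(protein = "dihedrals"))
  expect_equal(unname(only_dih), unname(backbone_dihedrals(traj, topo)),
               ignore_attr = TRUE)

  spec3 <- feature_spec("dihedrals", "shell_0.3nm", "lipid_weighted_distance")
  fm <- assemble_features(traj, topo, spec3)
  expect_equal(ncol(fm),
               ncol(backbone_dihedrals(traj, topo)) +
               ncol(solvent_shell_counts(traj, topo, "water_oxygen", 0.3)) +
               ncol(lipid_weighted_distance(traj, topo, 0.3)))
  expect_identical(unname(fm), unname(assemble_features(traj, topo, spec3)))
})

test_that("features follow their atom labels under atom-order permutation", {
  set.seed(9)
  roles <- c(rep("protein_heavy", 5), rep("water_oxygen", 20))
  coords <- matrix(runif(25 * 3, 0, 3), 25, 3)
  sys <- toy_system(roles, coords, box = c(6, 6, 6))
  fm <- solvent_shell_counts(sys$traj, sys$topo, "water_oxygen", 1.0)

  perm <- c(sample(1:5), sample(6:25)) # permute within each role block
  sys2 <- toy_system(roles[perm], coords[perm, ], box = c(6, 6, 6))
  ## give permuted atoms their original residue numbers so labels match
  sys2$topo$resno <- sys$topo$resno[perm]
  fm2 <- solvent_shell_counts(sys2$traj, sys2$topo, "water_oxygen", 1.0)
  expect_equal(fm2[1, colnames(fm)[order(colnames(fm))]],
               fm[1, colnames(fm)[order(colnames(fm))]])
})
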