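single_traj_set <- function(m, frame_interval = 0.5) {
  structure(list(trajectories = list(m), frame_interval = frame_interval,
                 seed = 1L, config_hash = "x"), class = "cv_trajset")
}

## A one-state MSM whose weights are uniform.
one_state_msm <- function() {
  structure(list(T = matrix(1, 1, 1), pi = 1, eigenvalues = 1,
                 right_vectors = matrix(1), left_vectors = matrix(1),
                 C = matrix(10, 1, 1), active = 1L, tau = 4.5,
                 iterations = 1L), class = "msm_model")
}

test_that("a single-state MSM reproduces the unweighted histogram exactly", {
  set.seed(3)
  m <- cbind(d = runif(300, 0.5, 2.2), theta = runif(300, -20, 60))
  cvs <- single_traj_set(m)
  states <- list(rep(1L, 300))
  w <- msm_weighted_histogram(cvs, states, one_state_msm(), bins = c(12, 12))
  raw <- msm_weighted_histogram(cvs, states, NULL, bins = c(12, 12))
  expect_equal(w$p, raw$p, tolerance = 1e-12)
  expect_equal(w$F, raw$F, tolerance = 1e-12)
  ## mass conservation and the min-shift convention
  expect_equal(sum(w$p, na.rm = TRUE), 1, tolerance = 1e-12)
  expect_equal(min(w$F, na.rm = TRUE), 0)
  expect_true(all(is.na(w$F[is.na(w$p)])))
})

test_that("a 2:1 occupancy ratio gives dF = kT log 2 exactly", {
  kT <- 0.5961
  m <- cbind(d = c(0.5, 0.5, 1.5), theta = c(0, 0, 0))
  cvs <- single_traj_set(m)
  fel <- msm_weighted_histogram(cvs, list(rep(1L, 3)), one_state_msm(),
                                bins = list(d = c(0, 1, 2), theta = c(-1, 1)),
                                kT = kT)
  expect_equal(fel$F[2, 1] - fel$F[1, 1], kT * log(2), tolerance = 1e-12)
  ## the shift leaves differences unchanged
  expect_equal(fel$F[1, 1], 0)
})

test_that("basin free energies obey symmetry, antisymmetry and label swaps", {
  sym <- synthetic_config(
    wells = list(well_spec(c(0.8, 0), 2.2, c(0.2, 10)),
                 well_spec(c(1.8, 0), 2.2, c(0.2, 10))),
    confinement_center = c(1.3, 0), confinement_strength = c(2, 0.002),
    n_trajectories = 60, frames_per_trajectory = 300, seed = 19)
  basins <- basin_definition(deep = list(d = c(0.3, 1.3), theta = c(-40, 40)),
                             shallow = list(d = c(1.3, 2.3), theta = c(-40, 40)))
  cvs <- sample_langevin(sym)
  fit <- cv_msm_fit(cvs, k = 15)
  dg <- basin_deltaG(cvs, fit$states, fit$msm, basins)
  expect_lt(abs(dg$delta_g), 0.12) # symmetric wells: dG = 0 within sampling error

  swapped <- basin_definition(deep = basins$shallow, shallow = basins$deep)
  dg2 <- basin_deltaG(cvs, fit$states, fit$msm, swapped)
  expect_equal(dg2$delta_g, -dg$delta_g, tolerance = 1e-12)

  far <- basin_definition(deep = list(d = c(0.3, 1.3), theta = c(-40, 40)),
                          shallow = list(d = c(90, 91), theta = c(-40, 40)))
  expect_error(basin_deltaG(cvs, fit$states, fit$msm, far), "zero-mass")
})

test_that("the designed two-well system recovers the quadrature dG", {
  cfg <- config_two_well(seed = 71)
  oracle <- exact_basin_populations(cfg, default_basins())
  cvs <- sample_langevin(cfg)
  fit <- cv_msm_fit(cvs, k = 20)
  dg <- basin_deltaG(cvs, fit$states, fit$msm, default_basins())
  expect_lt(abs(dg$delta_g - oracle$delta_g), 0.15)
})

test_that("dG error shrinks with the trajectory budget", {
  oracle <- exact_basin_populations(config_two_well(), default_basins())$delta_g
  budgets <- c(15L, 60L, 200L)
  med_err <- sapply(budgets, function(nt) {
    errs <- sapply(1:10, function(s) {
      cfg <- config_two_well(seed = 7000 + 17 * s, n_trajectories = nt,
                             frames_per_trajectory = 250L)
      cvs <- sample_langevin(cfg)
      fit <- cv_msm_fit(cvs, k = 15)
      dg <- basin_deltaG(cvs, fit$states, fit$msm, default_basins())
      abs(dg$delta_g - oracle)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) <= 0))
})

test_that("bootstrap CIs are deterministic and degenerate without resampling variability", {
  m <- cbind(d = rep(c(0.9, 1.7, 0.9, 1.7), each = 20) +
               rep(seq(-0.1, 0.1, length.out = 20), 4),
             theta = rep(c(5, 35, 5, 35), each = 20))
  ## two identical trajectories: resampling cannot change anything
  cvs <- structure(list(trajectories = list(m, m), frame_interval = 0.5,
                        seed = 1L, config_hash = "x"), class = "cv_trajset")
  states <- lapply(cvs$trajectories, function(x) as.integer(x[, 1] > 1.3) + 1L)
  dg <- bootstrap_deltaG(cvs, states, default_basins(), tau = 0.5,
                         frame_interval = 0.5, k = 2, B = 25, seed = 2)
  expect_equal(unname(dg$ci_range), 0, tolerance = 1e-12)

  cvs2 <- sample_langevin(small_two_well(seed = 73, n_trajectories = 25L,
                                         frames_per_trajectory = 150L))
  fit <- cv_msm_fit(cvs2, k = 12)
  b1 <- bootstrap_deltaG(cvs2, fit$states, default_basins(),
                         frame_interval = 0.5, k = 12, B = 50, seed = 4)
  b2 <- bootstrap_deltaG(cvs2, fit$states, default_basins(),
                         frame_interval = 0.5, k = 12, B = 50, seed = 4)
  expect_identical(b1$ci, b2$ci)
  expect_lte(b1$ci[1], b1$delta_g + 1e-12)
  expect_gte(b1$ci[2], b1$delta_g - 1e-12)
})

test_that("ddG is the difference of basin gaps and antisymmetric", {
  kT <- 0.5961
  mk <- function(dg_target) {
    n_deep <- 20000L
    n_shal <- as.integer(round(n_deep * exp(-dg_target / kT)))
    m <- cbind(d = c(rep(0.9, n_deep), rep(1.7, n_shal)),
               theta = c(rep(5, n_deep), rep(35, n_shal)))
    cvs <- single_traj_set(m)
    basin_deltaG(cvs, list(rep(1L, nrow(m))), one_state_msm(), default_basins(),
                 kT = kT)
  }
  a <- mk(0.9); b <- mk(1.9)
  expect_equal(a$delta_g, 0.9, tolerance = 1e-3)
  expect_equal(b$delta_g, 1.9, tolerance = 1e-3)
  expect_equal(delta_delta_G(a, b), 1.0, tolerance = 2e-3)
  expect_equal(delta_delta_G(b, a), -delta_delta_G(a, b), tolerance = 1e-12)
  expect_equal(delta_delta_G(a, a), 0)
})

test_that("water coordination counts match a brute-force loop", {
  dry <- toy_system(rep("protein_heavy", 2), rbind(c(1, 1, 1), c(2, 2, 2)))
  expect_equal(count_coordinating_waters(dry$traj, dry$topo, 1:2), 0L)

  one <- toy_system(c("protein_heavy", "water_oxygen"),
                    rbind(c(1, 1, 1), c(1, 1, 1.3)))
  expect_equal(count_coordinating_waters(one$traj, one$topo, 1L), 1L)

  set.seed(33)
  box <- c(3, 3, 3)
  roles <- c(rep("ligand_heavy", 4), rep("water_oxygen", 40))
  coords <- matrix(runif(44 * 3, 0, 3), 44, 3)
  sys <- toy_system(roles, coords, box = box)
  got <- count_coordinating_waters(sys$traj, sys$topo, 1:4, d_max = 0.5)
  brute <- 0L
  for (j in 5:44) {
    near <- FALSE
    for (i in 1:4) {
      dv <- abs(coords[j, ] - coords[i, ]); dv <- pmin(dv, box - dv)
      if (sqrt(sum(dv^2)) <= 0.5) near <- TRUE
    }
    brute <- brute + near
  }
  expect_equal(got, brute)
})

test_that("the reweighted landscape shows the two designed minima", {
  cvs <- sample_langevin(config_two_well(seed = 79, n_trajectories = 60L,
                                         frames_per_trajectory = 300L))
  fit <- cv_msm_fit(cvs, k = 15)
  fel <- msm_weighted_histogram(cvs, fit$states, fit$msm, bins = c(30, 30))
  mins <- find_local_minima(fel, depth_cutoff = 1.5, radius = 3)
  expect_equal(nrow(mins), 2)
  mins <- mins[order(mins$d), ]
  expect_lt(abs(mins$d[1] - 0.9), 0.2)
  expect_lt(abs(mins$d[2] - 1.7), 0.2)
  basins <- propose_basins(fel, depth_cutoff = 1.5, radius = 3)
  expect_s3_class(basins, "basin_definition")
  expect_lt(basins$deep$d[2], 1.7); expect_gt(basins$deep$d[2], 0.9)
})
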