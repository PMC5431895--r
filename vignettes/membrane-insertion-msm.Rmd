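---
title: "Estimating membrane-insertion free-energy landscapes from many short trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating membrane-insertion free-energy landscapes from many short trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memsm)
```

## The problem

Peripheral membrane proteins such as the PKC C1b domain associate reversibly
with one leaflet of a lipid bilayer, and the *position* of the bound complex
— how deep the binding site sits below the phosphate plane, and how tilted
the protein body is — can differ between ligands even when binding affinity
does not. Two coordinates summarize this geometry:

* **depth** `d` (nm): the signed distance of the binding-site centroid (the
  mean alpha-carbon position of M9, T12, L21 and V25) from the membrane
  mid-plane, positive toward the peptide-proximal leaflet;
* **tilt angle** `theta` (degrees): the angle between the membrane plane and
  the axis from that centroid to the distal centroid (mean of the alpha
  carbons of F3, G35 and N48 and the structural zinc), positive when the
  distal end points away from the membrane.

Equilibrium populations over `(d, theta)` cannot be read directly from a
histogram of short simulations: trajectories are far shorter than the slow
insertion/extraction kinetics, and they start wherever they were seeded. A
Markov state model (MSM) solves this: discretize configuration space into
states, count transitions at a lag time, estimate a reversible transition
matrix, and use its stationary distribution to reweight every frame. The
package implements the full chain:

1. **featurization** — seven base featurizers over protein, water and lipid
   degrees of freedom, combined one-or-none per subsystem into 35
   featurizations;
2. **tICA** — the slowest linearly decorrelating feature combinations, from
   the generalized eigenproblem `Cbar v = lambda (C00 + gI) v`;
3. **clustering** — mini-batch k-means in tIC space;
4. **reversible MSM** — maximum-likelihood transition matrix under detailed
   balance at a 4.5 ns lag;
5. **GMRQ model selection** — cross-validated scoring of how slowly the
   first `m = 6` eigenvectors decorrelate on held-out trajectories;
6. **landscapes and basin gaps** — MSM-reweighted 2-D free energy
   `F(d, theta) = -kT log p`, basin probabilities, `dG =
   -kT log(P_shallow / P_deep)`, and trajectory-bootstrap confidence
   intervals.

## The synthetic ground truth

No public trajectory set accompanies the biological system this pipeline is
designed around, so the package ships a generator whose answers are known
exactly. It works directly in `(d, theta)` space: a potential built from
inverted Gaussian wells plus a weak harmonic confinement,

```
U(d, theta) = sum_w -A_w exp(-(d-d_w)^2/(2 s_dw^2) - (theta-t_w)^2/(2 s_tw^2))
            + k_d (d - d_c)^2 + k_t (theta - t_c)^2 ,
```

sampled by overdamped Langevin dynamics (Euler–Maruyama,
`x+ = x - (D/kT) grad U dt + sqrt(2 D dt) xi`). Because `U` is analytic,
basin populations follow from 2-D quadrature (`exact_basin_populations()`),
giving an exact reference for every downstream estimate.

Two presets define the study conditions:

* `config_two_well()` — a deep well at `(0.9 nm, 5 deg)` (amplitude 3.0
  kcal/mol) and a shallower, more tilted well at `(1.7 nm, 35 deg)`
  (amplitude 1.515 kcal/mol), calibrated once against the quadrature oracle
  so the ground-truth basin gap is 0.90 kcal/mol — the regime of a ligand
  stabilizing both a deep and a shallow orientation;
* `config_deep_biased()` — the same geometry with amplitudes 4.004 and 1.0
  kcal/mol, giving a 1.90 kcal/mol gap — a ligand that strongly favors deep
  insertion. Weakening the shallow well alone cannot produce a gap this
  large (the confinement background floors the shallow-basin mass near 1.4
  kcal/mol), which is why this preset deepens the main well instead.

Remaining defaults, and why:

* `kT = 0.5961` kcal/mol (300 K);
* widths `(0.20 nm, 12 deg)` — comparable to the apparent basin widths of
  typical insertion landscapes, and wide enough that a 40 x 40 histogram
  resolves each well;
* diffusion `(0.03 nm^2/ns, 120 deg^2/ns)` — relaxation inside a well takes
  a few hundred ps while the slowest interwell process relaxes with
  `t_2 ~ 9.5 ns` (computed spectrally from the discretized diffusion
  generator), so the 4.5 ns MSM lag sits below the slow timescale and far
  above the fast ones;
* 200 trajectories x 500 frames at 0.5 ns per frame (250 ns each, 50 us
  aggregate) — many-short-trajectory data of the kind distributed computing
  produces, long enough in aggregate for tens of interwell transitions in
  each direction;
* integrator step 0.01 ns (50 substeps per frame). The Euler–Maruyama
  scheme has an O(dt) stationary bias that we measured directly against a
  Metropolis Monte Carlo control: about -0.7*dt kcal/mol on the basin gap.
  At 0.01 ns the bias (~ -0.007 kcal/mol) is far below sampling noise;
* start rule `"span"`: starts evenly spaced along the segment through the
  well centers, extended 20% past each end — emulating seeding from a
  pulling run across the insertion coordinate, and deliberately *not*
  equilibrium-distributed, which is exactly the situation MSM reweighting
  exists to fix.

The toy atomistic embedding (`embed_frames()`) realizes each `(d, theta)`
pair as coordinates: a rigid 50-residue pseudo-peptide (backbone N/CA/C,
alpha carbons with the field's residue numbering, a structural zinc, a ring
of ligand heavy atoms), lipid phosphorus markers on jittered lattices at the
two leaflet planes, and water oxygens whose density is bulk-like outside the
headgroup region, decays linearly through it, and vanishes in the
hydrocarbon core. The peptide is placed relative to the *realized* leaflet
planes of each frame, so `compute_cv()` recovers the inputs to 1e-6 nm and
1e-4 degrees — an exact round trip rather than an approximate one. The
embedding is deliberately minimal: no lipid tails, no explicit hydrogens, no
electrostatics. It provides exactly the geometric structure the featurizers
consume, nothing more, so passing tests certify the analysis machinery — not
any molecular mechanics.

## Numerical choices that matter

* **tICA estimator.** Lagged pairs use a sliding window and never cross
  trajectory boundaries; the mean and instantaneous covariance are computed
  over both ends of the pair ensemble, and the lagged covariance is
  symmetrized — this keeps all eigenvalues real and `|lambda| <= 1`.
  Regularization adds `g I` to the instantaneous covariance (a ridge on the
  metric). Component signs are fixed by making each component's
  largest-magnitude loading positive.
* **Reversible MLE.** The classic self-consistent iteration on symmetrized
  pair counts, tolerance `max|dT| < 1e-10`, cap 1e6 iterations. Detailed
  balance holds exactly at every iterate by construction; the eigensystem
  is computed through the `D^{1/2} T D^{-1/2}` similarity so the spectrum is
  real. States outside the largest strongly connected component of the
  count graph are trimmed first (a stationary distribution is undefined
  otherwise).
* **GMRQ.** The scored eigenvectors come from the variational
  (symmetrized-count) estimator of the training data, for which the
  self-scored value equals the sum of the first `m` training eigenvalues
  exactly — the identity the suite asserts at 1e-8. `m = 6` includes the
  stationary eigenvector. Test matrices are the empirical symmetrized
  correlation and overlap matrices of the held-out state sequences; states
  never visited in the test set contribute zero rows, with a pseudo-inverse
  and a rank warning when the overlap degenerates. Splits are 50%
  shuffle-splits at trajectory granularity.
* **Landscape and basins.** 40 x 40 bins over the sampled range padded 5%;
  empty bins are `NA`, never zero free energy. Basins are half-open
  rectangles, so abutting deep/shallow definitions partition the plane.
  `dG = -kT log(P_shallow/P_deep)` is positive when the shallow state is
  less populated. A helper proposes rectangles from the two lowest local
  minima; production analyses should state their basins explicitly.
* **Bootstrap.** Resamples trajectories, not frames, to respect
  autocorrelation; tICA and clustering stay fixed across replicates, and
  each replicate refits only the reversible MSM from the resampled counts.
  The percentile interval uses the `(B+1) alpha` order-statistic convention
  of the classic bootstrap literature. Replicates with an empty basin are
  dropped and counted; more than 20% dropped is an error, not a silent
  narrowing of the interval.
* **Quadrature oracle.** Each region (normalization domain, deep rectangle,
  shallow rectangle) is integrated on its own tensor grid so every
  integrand is smooth (O(h^2) trapezoid convergence); grid doubling stops
  when populations change by less than 1e-6 relative (with a 1e-10 absolute
  floor for numerically-zero masses).

## What the tests do and do not show

The suite checks every operation against an independent oracle — explicit
pair enumeration for histograms and neighbor counts, a rotation-grid search
for superposition RMSD, a dense generalized eigensolver for tICA, a
likelihood grid search and analytic two-state results for the reversible
MSM, Tarjan's algorithm for the ergodic trimming, quadrature for every
free-energy quantity — and then exercises the full pipeline: recovery of the
0.90 kcal/mol ground-truth gap within 0.15 kcal/mol at the reference
conditions, a smaller L1 distance to the exact landscape after reweighting
than before it on biased-start data, and 95% bootstrap intervals covering
the true gap in 45 of 50 independent datasets (B = 100). Problem sizes in
the suite are chosen to finish in minutes: the coverage experiment uses the
full reference conditions, while unit-level tests run the same physics at
30-60 trajectories.

Because the generator works in collective-variable space with pseudo-atoms,
these results certify the statistical machinery — featurization geometry,
tICA algebra, MSM estimation, reweighting, and uncertainty quantification —
under a known ground truth. They do not certify force fields, sampling
adequacy of any real system, or the behavior of the featurizers on chemistry
the toy embedding lacks (hydrogens, lipid tails, counterions). On real data
the analyst must still check implied-timescale convergence in the lag time
and inspect the GMRQ surface before trusting a landscape.

## Design decisions that were genuinely open

* Nothing fixes the functional form of the ground-truth potential beyond
  the qualitative two-well landscape it must emulate; Gaussian wells plus
  harmonic confinement were chosen for analytic gradients and
  quadrature-friendly tails.
* "Water density within a radius" is implemented as a raw count within the
  shell (density times a constant shell volume); volume normalization would
  only rescale each feature column and cannot change tICA projections.
* The weighted lipid-distance featurizer uses `sum_j exp(-d_ij / sigma)`
  with `sigma = 0.3` nm: smooth, bounded, monotone in proximity.
* The reciprocal-distance "distribution" is a fixed 50-bin normalized
  histogram on [0, 10] nm^-1.
* RMSD superposes protein heavy atoms (not all atoms); the reference is the
  first frame of the first trajectory unless supplied.
* tICA is fit pooled over trajectories, the standard choice for MSM
  pipelines; per-trajectory fits would make the state decomposition
  split-dependent.
* Angle is treated as an unbounded coordinate confined by the potential (no
  periodic wrap); the physical range stays within [-90, 90] degrees.
* Sliding-window (not strided) transition counts — lowest variance.
* The hyperparameter search is an exhaustive grid (with per-combination
  derived seeds); a fancier optimizer would change only the search path,
  not the score definition.
* The GMRQ scoring direction follows the held-out data (training on one
  subset, scoring on the other); scoring the training subset would make the
  cross-validation circular.

## Known limitations

* Orthorhombic boxes only (minimum-image convention); no triclinic support.
* No Bayesian MSM posteriors, hidden Markov models, or PCCA coarse-graining;
  uncertainty comes from the trajectory bootstrap alone.
* The water-coordination count is a distance-only contact criterion — the
  pseudo-waters carry no hydrogens, so no donor-angle term is possible.
* Free energies are equilibrium-only: no rates or mean first-passage times
  between basins are reported.

## A minimal run

```{r example, eval = FALSE}
cfg <- validate_config(list(
  seed = 1,
  output_dir = "run1",
  synthetic = list(n_trajectories = 40, frames_per_trajectory = 200),
  tica = list(t_grid = c(0.5, 2), g_grid = c(1e-4, 1e-7)),
  cluster = list(k_grid = c(10, 20)),
  gmrq = list(n_repeats = 2),
  landscape = list(bins = c(25, 25)),
  deltag = list(B = 100)))
manifest <- run_pipeline(cfg)
```

The run directory then holds `cv_ground_truth.csv`, `gmrq_scan.csv`,
`tica_model.json`, `landscape.csv`, `deltag.json` and a `manifest.json`
whose checksums make the run reproducible; re-running with an unchanged
configuration is a no-op.
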