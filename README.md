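# memsm

Markov state modelling of peripheral membrane-protein insertion depth and
tilt, in R.

## The problem

Peripheral membrane proteins — the PKC C1b domain bound to diacylglycerol
mimetics is the motivating case — associate reversibly with one bilayer
leaflet, and different ligands can stabilize *different positions* of the
bound complex: a deeply inserted, upright orientation versus a shallow,
tilted one. The natural summary coordinates are the insertion depth `d` (nm,
binding-site centroid to membrane mid-plane) and the tilt angle `theta`
(degrees, long axis of the protein against the membrane plane). The
equilibrium free-energy surface `F(d, theta) = -kT log p(d, theta)` and the
gap between its basins,

```
dG = -kT * log(P_shallow / P_deep)   [kcal/mol]
```

quantify how strongly a ligand favors one orientation. With many short
simulations, raw histograms are biased by where trajectories started; a
reversible Markov state model (MSM) built on the trajectories supplies
stationary weights that remove that bias.

`memsm` implements the full analysis chain as reusable, tested functions:

| stage | functions |
|---|---|
| synthetic ground truth (two-well Langevin, toy atomistic embedding) | `config_two_well()`, `sample_langevin()`, `embed_frames()`, `exact_basin_populations()` |
| featurization (7 featurizers, 35 combinations) | `enumerate_combined_featurizations()`, `assemble_features()`, `featurize_dataset()` |
| tICA with L2 regularization | `fit_tica()`, `tica_transform()` |
| clustering + reversible MSM at 4.5 ns lag | `fit_minibatch_kmeans()`, `build_msm()`, `implied_timescales()` |
| GMRQ cross-validated model selection | `shuffle_split()`, `gmrq_score()`, `hyperparameter_search()`, `top_featurizations()` |
| landscapes, basin dG, bootstrap CIs | `compute_cv()`, `msm_weighted_histogram()`, `basin_deltaG()`, `bootstrap_deltaG()` |
| orchestration | `validate_config()`, `run_pipeline()` |

Because the reference trajectory data for the biological system are not
publicly deposited, the package ships a generator with exactly known
answers: a two-well potential on `(d, theta)` sampled by overdamped Langevin
dynamics, plus a pseudo-atomistic embedding (peptide rigid body, lipid
phosphorus planes, density-graded waters) so every featurizer and the
collective-variable geometry can be tested against exact oracles. See the
vignette `vignettes/membrane-insertion-msm.Rmd` for the model, parameter
choices, and what the tests do and do not establish.

## Worked example

Recover the ground-truth basin gap of the reference two-well condition:

```r
library(memsm)

cfg    <- config_two_well(seed = 1)            # 200 trajectories x 500 frames
oracle <- exact_basin_populations(cfg, default_basins())
cvs    <- sample_langevin(cfg)

feats  <- lapply(cvs$trajectories, function(m)
  memsm:::feature_matrix(m[, 1:2], c("d", "theta"), cvs$frame_interval))
tica   <- fit_tica(feats, lag = 2, g = 1e-6, n_components = 2)
tics   <- tica_transform(tica, feats)
cm     <- fit_minibatch_kmeans(tics, k = 20, seed = 2)
states <- assign_states(cm, tics)
msm    <- build_msm(states, tau = 4.5, frame_interval = 0.5, k = 20)

dg <- basin_deltaG(cvs, states, msm, default_basins())
round(c(estimate = dg$delta_g, truth = oracle$delta_g), 3)
#> estimate    truth
#>    0.879    0.900
```

The estimate (here 0.879 kcal/mol; the exact value depends on the seed) agrees
with the quadrature ground truth of 0.900 kcal/mol to well within the
sampling error of a 50 microsecond aggregate. `bootstrap_deltaG()` adds a
95% percentile interval from trajectory resampling, and
`msm_weighted_histogram()` + `plot()` render the reweighted landscape.

A configured end-to-end run (synthesis, GMRQ scan over `(t, g, k)`, refit,
landscape, basin gap) is one call:

```r
manifest <- run_pipeline(list(seed = 1, output_dir = "run1"))
```

`inst/scripts/run_pipeline.R` wraps the same call for shell use
(`Rscript inst/scripts/run_pipeline.R --config cfg.yaml --seed 1`).

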