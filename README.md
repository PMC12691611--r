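# mxquant

Quantitative analysis of type IVa pilus (T4aP)-driven bacterial surface
motility, fluorescence colocalization, and equilibrium carbohydrate–pilin
binding — with paired synthetic-data generators so that every statistic
can be validated by parameter recovery.

The package is aimed at microbiologists and image analysts studying
social/twitching motility in rod-shaped bacteria such as *Myxococcus
xanthus*, where cells move by pilus retraction, deposit exopolysaccharide
(EPS) trails that constrain their neighbours, and where pilin–sugar
affinities (from SPR and ITC) underpin the motility phenotype.

## What it computes

**Motility.** An agent-based simulator produces movies of capsule-shaped
cells following a persistent random walk with Poisson reversals and
optional EPS-trail following, together with ground-truth trajectories.
A classical detection/tracking pair (Otsu threshold + connected
components + second-moment ellipses; Hungarian frame-to-frame linking)
turns movies into tracks. From tracks the package computes:

* instantaneous velocities, pooled per step:
  `v = |Δx| / Δt` (µm/min);
* percent reduction between group means, `100·(v̄_ref − v̄_test)/v̄_ref`;
* pooled-variance Student's *t* for two velocity populations;
* cumulative surface coverage: the union of discs of radius equal to each
  cell's minor semi-axis stamped at every detection, as a fraction of the
  arena;
* Gaussian-smoothed 2-D density heatmaps of cell centers
  (mass-conserving by construction).

**Colocalization.** For a two-channel image pair: Manders overlap
coefficients M1/M2, Pearson's correlation coefficient, and the intensity
correlation quotient (ICQ), over an optional mask with Otsu or explicit
thresholds.

**Binding.** Steady-state SPR responses are fit to the 1:1 Langmuir
isotherm `Req = Rmax·C/(K_D + C)`; ITC thermograms (19 × 2 µL injections
into a 300 µL cell by default) are corrected by control-titration
subtraction and fit to the one-set-of-sites model with
volume-displacement–corrected concentrations, returning the
stoichiometry *n*, `K_D` and ΔH.

## Worked example

```r
library(mxquant)

## simulate a wild-type-like movie: 30 cells, 1,000 s at 10 s intervals,
## speeds 10.36 +/- 5.03 um/min
cfg <- motility_sim_config(arena_width = 100, arena_height = 100,
                           n_cells = 30, duration = 1000,
                           speed_mean = 10.36, speed_sd = 5.03, seed = 1)
traj  <- simulate_trajectories(cfg)
movie <- render_frames(traj, pixel_size = 0.5, psf_sigma = 0.2,
                       noise_sd = 0.03, seed = 1)
movie
#> <frame_stack: 101 frame(s) of 200 x 200 px, 0.5 um/px, dt = 10 s>

tracks <- track_stack(movie)
instantaneous_velocities(tracks)
#> <velocity_profile: 2811 steps, mean 10.17 +/- 5.15 um/min>
cumulative_coverage(tracks, grid_pixel_size = 0.5)
#> <coverage_map: 200 x 200 px, coverage 24.9%>
```

The tracked population mean (10.17 µm/min) recovers the generating mean
(10.36) to about 2%; the coverage map is the fraction of the arena the
population's footprints visited during the movie. Comparing two group
means the way motility studies report it:

```r
percent_reduction(10.36, 6.02)
#> [1] 41.89
```

Binding-model recovery from synthetic data at realistic noise:

```r
itc <- generate_itc_dataset(itc_sim_config(n = 1.47, K_D = 3e-4, dH = -5,
                                           noise_sd = 0.1, seed = 1))
fit_itc_one_site(subtract_dilution(itc))
#> <itc_fit: n = 1.386, K_D = 0.0003381 M, dH = -5.315 kcal/mol, c = 4.1>

spr <- generate_spr_dataset(spr_sim_config(
  Rmax = 100, K_D = 1.055e-3,
  concentrations = spr_twofold_series(extend_to_kd = 1.055e-3),
  noise_sd = 2, seed = 1))
fit_spr_steady_state(spr)
#> <spr_fit: K_D = 0.001071 M, Rmax = 101.7 RU, RSS = 19>
```

A YAML-driven pipeline runner (`run_pipeline()`) chains
simulate → track → quantify and writes all artifacts plus a
`summary.json` with full seed provenance; a thin CLI wrapper lives at
`inst/scripts/mxquant-cli.R` with a demo config in
`inst/extdata/demo-motility.yaml`.

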