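---
title: "Models and methods behind mxquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mxquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxquant)
```

mxquant quantifies type IVa pilus (T4aP)-driven single-cell motility of
rod-shaped bacteria such as *Myxococcus xanthus*, computes colocalization
statistics for two-channel fluorescence images, and fits 1:1 equilibrium
binding models to surface plasmon resonance (SPR) and isothermal titration
calorimetry (ITC) data. Every analysis has a paired synthetic-data
generator, so each statistic can be validated by recovering the parameters
that generated its input. This vignette documents the models, the
parameters that matter, and the design choices made where the design was
genuinely open.

## The motility simulator

Cells are points with an orientation and a capsule-shaped body (length
about 5 µm, width about 0.8 µm by default) moving in a rectangular arena.
Movies follow the standard single-cell assay geometry: 1,000 s of
observation at 10 s frame intervals. The kinematic model is a persistent
random walk:

* **Speeds.** Per-step speeds are drawn from a normal distribution
  truncated at zero. Published motility summaries report only a mean and
  SD (for example 10.36 ± 5.03 µm/min for wild-type cells and
  6.02 ± 3.32 µm/min for a binding-deficient pilin variant), so the
  truncated normal is the simplest non-negative model matching those two
  moments. Naively using the reported mean/SD as the *parent* parameters
  would inflate the realised mean by roughly 2–4% (truncation removes the
  negative tail), so `truncnorm_match_moments()` solves for parent
  parameters whose *truncated* distribution has exactly the configured
  mean and SD. The configured moments are therefore the generated moments,
  which is what parameter-recovery testing requires.
* **Headings.** The heading evolves by a wrapped-normal perturbation with
  SD `(1 - persistence) * pi` per step; `persistence = 1` gives straight
  runs. Reversals — a documented behaviour of *M. xanthus* — are
  instantaneous 180° flips occurring at exponential waiting times with
  rate `reversal_rate` (events/s).
* **Trail following.** Cells secrete exopolysaccharide (EPS) trails that
  constrain the trajectories of neighbours. The simulator models trails as
  a shared occupancy raster: each frame every cell deposits along its body
  axis, the raster decays by `trail_decay` per frame, and headings are
  steered toward the look-ahead direction (±60° fan) with the densest
  trail, mixed with the current heading by `trail_following_strength`.
  No quantitative trail-decay or bias values are published; the parameters
  are exposed and the package claims only the directional consequence,
  verified at fixed seeds: trail following reduces unique-area exploration
  at matched speeds.
* **Boundaries.** Reflective. The real field of view is open, but
  reflection keeps the population density stationary without immigration
  bookkeeping; the choice is configurable in the sense that an arena much
  larger than the diffusion length makes it irrelevant.

Ground truth records per cell and frame the centroid, axial orientation,
body dimensions, and the generating speed of the step leading into the
frame. Displacement-based speeds equal these generating speeds except
across a boundary bounce, where the chord is shorter than the path.

## Rendering, detection and tracking

`render_frames()` draws each cell as an oriented capsule (rectangle with
semicircular caps), blurs with a Gaussian point-spread function, and adds
Gaussian noise. Pixel centers sit at `(i - 0.5) * pixel_size` with the
origin at the top-left and x along columns; all public coordinates are µm.

`segment_frame()` is a deliberately classical stand-in for a learned
detector, preserving the same input/output contract: global threshold
(Otsu's criterion by default), connected-component labelling (EBImage),
and a second-moment ellipse per component. Axes are the standard
`4 * sqrt(eigenvalue)` moment lengths with the pixel-extent correction
(`pixel_size^2 / 12`); orientation is axial in `[0, π)` because cell ends
are indistinguishable. Components smaller than `min_area` are noise;
components larger than `max_area` (off by default) can be rejected to
suppress merged blobs of touching cells — with the filter on, transient
contacts become short gaps that the tracker bridges, rather than
ambiguous detections.

`link_tracks()` performs frame-to-frame globally optimal one-to-one
assignment by the Hungarian method (a Jonker–Volgenant shortest
augmenting path implementation in C++), with cost
`distance + morphology_weight * |Δarea| / mean(area)` and links beyond
`max_link_distance` forbidden. Global assignment rather than greedy
nearest-neighbour matching mirrors the globally consistent linking role
that a learned tracker plays. Unmatched detections seed new tracks;
tracks unseen for more than `max_gap_frames` frames terminate; gap-spanning
links carry a flag. Ties are impossible in exact arithmetic and the solver
is deterministic, so identical inputs give identical tracks.

## Motility metrics

* **Instantaneous velocities** are per-step displacements divided by the
  frame interval, in µm/min, pooled across tracks at step level. Pooling
  at step level (rather than per-track means) matches the granularity of
  violin-plot velocity profiles; per-track aggregation is available via
  `per_track_means = TRUE`. Steps spanning gaps are excluded.
* **Percent reduction** is `100 * (reference - test) / reference`,
  reported to 2 decimals; with the published group means (10.36,
  6.02 µm/min) it reproduces the published 41.89%.
* **Student's t** uses the pooled-variance form (`t.test(var.equal =
  TRUE)`), following the usual naming in the motility literature; Welch's
  variant is deliberately not substituted. Degenerate zero-variance inputs
  use documented conventions (t = 0, p = 1 for equal means; p = 0
  otherwise).
* **Cumulative surface coverage** stamps, for every detection, a disc at
  the centroid onto an arena raster and accumulates the union over frames.
  The footprint rule in the source protocol ("an ellipse with the
  short-axis length used as the radius") is ambiguous; the disc radius
  here is the minor *semi*-axis (half the fitted width), because a disc is
  the only shape consistent with a radius and the semi-axis avoids
  double-width footprints. `radius = "minor"` selects the full-width
  alternative. A pixel is covered when its center lies inside the disc,
  which makes the implementation exactly equal to a brute-force per-pixel
  oracle.
* **Density heatmaps** are 2-D histograms of centroids smoothed with a
  normalized Gaussian kernel under reflect padding. Reflect padding makes
  the smoothing operator column-stochastic, so the array sum equals the
  number of points exactly — a testable conservation invariant.

## Colocalization

`coloc_stats()` computes the four standard statistics over an optional
mask: Manders M1/M2 (fraction of one channel's intensity on pixels where
the other exceeds its threshold), Pearson's correlation coefficient, and
the intensity correlation quotient (fraction of nonzero
mean-deviation products that are positive, minus 0.5). Design choices:

* Thresholds default to Otsu per channel, with explicit overrides —
  reproducible where the original plugin settings are unknown.
* Pixels with a zero ICQ product are excluded from numerator and
  denominator, which makes the ±0.5 limit cases exact.
* Constant channels make PCC/ICQ undefined and raise errors rather than
  returning 0, so silent degenerate inputs cannot masquerade as absence
  of correlation.

The paired generator places disc objects uniformly for channel 1 and puts
a configurable fraction of channel-2 objects exactly on channel-1 centers,
returning ground-truth masks. It emulates partially overlapping punctate
two-channel signals; it does not emulate chromatic aberration,
bleed-through, or structured backgrounds, so passing tests demonstrate
correctness of the statistics, not robustness to those artefacts.

## Binding models

**SPR steady state.** Equilibrium responses follow the 1:1 Langmuir
isotherm `Req = Rmax * C / (K_D + C)`. Fitting uses Levenberg–Marquardt
on log-parameterised `(Rmax, K_D)` (positivity by construction), started
from `Rmax0 = 1.1 * max(response)` and `K_D0 = median(C)`. Fits are
flagged unreliable when the solver fails or `K_D` leaves
`[min(C)/100, 100 * max(C)]` — outside that window the data cannot
constrain the constant. Full kinetic (on/off-rate) fitting is out of
scope; published affinities here are steady-state. The default analyte
series is a twofold ladder from 31.25 µM; `spr_twofold_series(extend_to_kd =)`
extends it past twice a target `K_D`, since sampling beyond
half-saturation is what makes `K_D` identifiable.

**ITC one set of sites.** With total site concentration `n * M_t`, total
ligand `X_t` and dissociation constant `K_D`, the complex concentration is
the usual quadratic root, and the heat of injection *i* is
`ΔH * V0 * ([MX]_i - f * [MX]_(i-1))` normalized per mole of injectant.
The concentration bookkeeping uses the instantaneous-mix overflow model:
an injection of volume *v* mixes into `V0 + v` and *v* overflows, so every
pre-existing species is retained by `f = V0 / (V0 + v)` per injection.
Published protocols rarely state their dilution model; this form is fixed
here and unit-tested against an independent oracle that solves the binding
equilibrium numerically. Defaults follow the standard geometry of 19 × 2 µL
injections into a 300 µL cell.

Control (ligand-into-buffer) titrations are subtracted elementwise by
`subtract_dilution()`. After that correction the baseline is zero by
construction, so `fit_itc_one_site()` does *not* fit a residual offset by
default: on noisy synthetic titrations a free offset trades off strongly
against `K_D` (median recovery error grows an order of magnitude), while
the offset is available via `fit_offset = TRUE` for titrations whose
dilution heats were never measured. Fits with a Wiseman c-parameter
(`n * M_t / K_D`) below 0.1 are flagged low-confidence. The enthalpy for
glucosamine binding is not published; generators default to −5 kcal/mol
and always record the value used. The macromolecule cell concentration is
likewise not published, so synthetic titrations carry their own (default
1 mM, giving c ≈ 5 for the glucosamine-like parameter set) and no claim is
made to match raw thermogram amplitudes.

## What the synthetic data do and do not show

The generators reproduce the *statistical* structure of the assays:
speed moments, persistence and reversals, trail constraint, capsule
geometry and imaging blur/noise, Langmuir plateaus over a twofold ladder,
and one-site thermograms with dilution offsets. They do not reproduce
mechanistic pilus force generation, cell–cell collision mechanics, uneven
illumination, focus drift, or polymer-specific multivalent binding.
Passing recovery tests therefore validates the estimators and the
pipeline plumbing on data that satisfy the model assumptions; they do not
certify performance on real micrographs with artefacts outside the model.

## Numerical choices and degenerate inputs

* Truncated-normal sampling uses the inverse-CDF transform, so the RNG
  stream length is input-independent and runs are bit-reproducible.
* All generators are deterministic given a config and seed.
* Assignment ties (exactly equal costs) are resolved deterministically by
  the solver's scan order (lowest index first).
* Flat or empty frames segment to zero detections, not errors; empty
  trajectory sets yield zero coverage and zero-speed profiles.
* A zero-enthalpy thermogram is unidentifiable and rejected; constant
  fluorescence channels are rejected for PCC/ICQ.
* The coverage raster and its oracle use the identical pixel-center
  membership rule, so their equality is exact, not approximate.

## Problem sizes used in validation

The package's own validation runs use 100 cells observed for 1,000 s at
10 s intervals for the full tracking chain (the standard assay scale),
10 replicates for each binding-model recovery, 256 × 256 grids for the
coverage oracle, and 20 replicates per overlap level for the
colocalization monotonicity check. These sizes make every recovery check
statistically meaningful at its intended tolerance while keeping a full
validation run on a laptop in minutes.

## Known limitations

* The detector has no shape model: strongly curved cells, dividing cells
  and persistent cell clusters are out of scope, as is any learned
  component.
* Coverage values depend on the footprint rule; published coverage
  percentages from real data are not reproduction targets because the
  original images and exact footprint convention are unavailable.
* The colocalization module quantifies overlap only; it performs no
  registration, deconvolution, or automatic (Costes-style) thresholding.
* The ITC model has a single class of independent sites; sequential or
  multi-site models are not provided.
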