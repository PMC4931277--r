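---
title: "A shape-memory model of asymmetric neural progenitor division"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A shape-memory model of asymmetric neural progenitor division}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapemem)
```

## The question the model addresses

Zebrafish V2 spinal progenitors divide once and produce two daughters with
different fates: an excitatory V2a and an inhibitory V2b interneuron. The
fate outcome is biased by the *shape* of the mother cell before it rounds
up for mitosis: cells with an asymmetric elongation (a spiky process on
one side) preferentially place the V2a daughter on the side the process
pointed to. Between the shape readout (before rounding) and the fate
decision (after division) lies mitotic rounding, during which the cell
becomes a sphere and apparently erases its shape. `shapemem` implements a
mechanistic answer to how the shape information survives: membrane-bound
Delta ligand is deposited preferentially on membrane regions far from the
cell center, diffuses on the cell surface while the cell rounds, and the
daughter that inherits more Delta at division wins the Delta-Notch
lateral-inhibition competition and takes the V2a fate.

The package has three layers:

1. **Shape metrics** (`shape_descriptor()`, `theta_fate()`,
   `localization_descriptor()`, `roc_threshold()`, `sav_ratio()`): voxel
   morphometry of segmented 3D cells, including the eccentricity index
   used throughout.
2. **Simulator** (`run_mcs()`, `divide_cell()`, the particle layer, and
   `resolve_fate()`): a 3D cellular Potts model of one cell with two
   species of membrane-bound particle agents and a two-cell ordinary
   differential equation for the fate switch.
3. **Experiment drivers** (`run_division_ensemble()`, `sweep_fig4()`,
   `calibrate_units()`, `fit_mode()`): seeded ensembles, chi-squared
   statistics against the 50:50 null, and physical-unit conversion.

## Shape metrics

A segmented cell is a voxel mask with physical spacing. Every foreground
voxel is a unit point mass at its center; the moment-of-inertia tensor
about the center of mass `C_mass` gives principal axes. The eigenvector
with the *smallest* eigenvalue is the long axis `e_long` (mass far from
an axis raises the moments about the other two). The principal-axis
aligned bounding box has center `C_median`; the **asymmetry vector**
`D_asym = C_median - C_mass` points toward the spiky side of the cell,
and each axis is sign-flipped so its dot product with `D_asym` is
nonnegative, defining the oriented axes `a_long`, `a_middle`, `a_short`
and the cell's (+) side. The scalar

```
D_long = D_asym . a_long        A_long = D_long / r,   r = (3V / 4 pi)^(1/3)
```

is the **asymmetric elongation index**: dimensionless, zero for any
centrosymmetric shape, invariant under rigid motion and uniform scaling.
Observed V2 cells span `A_long` 0 to about 0.12.

The fate axis `a_CD` points from the V2b daughter to the V2a daughter;
`cos(theta_fate) = a_long . a_CD > 0` means the (+)-side daughter took
the V2a fate. Protein localization is summarized by the intensity-weighted
centroid offset from `C_mass`, normalized by `r` (`d_norm`), with the side
given by the sign of the projection on `a_long`. All of these are exact
voxel sums; the test suite checks them against brute-force summation,
analytic digitized ellipsoids (axis error below 2 degrees, eigenvalue
error below 3 percent at 20+ voxels per axis) and planted synthetic
stacks.

Degenerate cases are flagged, not guessed: a near-isotropic tensor (the
two smallest eigenvalues within a relative `tol` of each other) sets
`degenerate`, and a vanishing `D_asym` keeps the raw eigenvector signs.
`A_long` is then 0 by construction. Exactly orthogonal fate and long axes
return a `"tie"` rather than an arbitrary call.

## The cellular Potts model

The lattice is a cubic grid of 0.5 um sites (close to the 0.42 x 0.42 x
0.89 um confocal voxel), each holding a cell identifier (0 = medium). The
energy is

```
H = sum_interfaces J  +  lambda_v (v - V)^2  +  lambda_s (s - S)^2
```

with interfaces counted over 6-adjacent site pairs of unequal identifier,
`v` the site count and `s` the exposed-face count of the cell. Metropolis
dynamics copy a random site's identifier into a random 26-neighbour,
always when the energy drops and with probability `exp(-dH / T)`
otherwise (`dH = 0` is accepted, since `exp(0) = 1`); one Monte Carlo
step (mcs) performs as many attempts as there are lattice sites. The
outermost one-site shell is frozen medium.

Mitotic rounding is induced by setting the target volume to the current
volume and the target surface to the area of the volume-equivalent
sphere. On a cubic lattice the face-counted area of a digitized smooth
sphere is about 1.5 times `4 pi r^2` (each surface patch is counted by
its three axis projections), so the target is scaled by a configurable
`surface_correction` (default 1.5, the measured digital-sphere ratio) to
make the sphere the actual minimizer. The cell divides at the first
crossing of the trigger surface `S_division` from above; because thermal
roughening lifts the face count within the first couple of steps, the
trigger *arms* once the surface has been above it at the end of a step
and fires at the next end-of-step surface at or below it. Division takes
place along the plane through the cell centroid perpendicular to the
cell vector (below); sites exactly on the plane alternate between the
daughters to balance volumes, and the daughters keep their shapes
(targets reset to their actual volumes and surfaces) while the fate
decision runs, up to the overall cap of 500 mcs.

### Parameter choices and the division-time calibration

The published description does not include numerical values for `J`,
`lambda_v`, `lambda_s`, `T` or `S_division`, so these are calibration
choices of this package (all exposed in `cpm_params()`). The defaults are
`J_cell_medium = 2`, `J_cell_cell = 1`, `lambda_v = 2`, `lambda_s = 0.2`,
`T = 16`, `S_division = 1.2 x S`. Volume is then conserved within a few
sites, the acceptance rate sits near half a percent, and all six fixture
shapes - which are built with equal elongation and equal initial surface
area (about 2410 faces against a spherical target of about 1885) - shed
surface steadily and divide 16-26 mcs after the start of rounding.

The division time is the one place where this implementation deliberately
departs from the source's reported average of 215 mcs, and the reason is
a timescale argument that can be checked with the package itself. A
yellow particle hops once per mcs to a boundary site in the annulus
`(s - 0.5, s + 0.5)` lattice lengths, so its surface diffusion
coefficient is `D = s^2 / 4` sites^2/mcs. On the sphere of radius ~10
sites the slowest (l = 1) relaxation mode of any surface polarization
decays with `tau = r^2 / (2 D)`, about 56 mcs at step 2. Division at 215
mcs is nearly four relaxation times: direct measurement
(`init_particles_shape_weighted()` followed by `run_mcs()`) shows the
(+)-side particle share collapsing from 0.55 to 0.50 well before 215 mcs
on a 10-um cell, which erases the fate bias, the diffusion-rate ordering
and the division-orientation alignment alike. A memory mechanism built on
surface diffusion only works if division happens within roughly one
mixing time, so the trigger is calibrated to fire inside the rounding
transient (~20 mcs). The physical-unit conversions
(`calibrate_units()`) still use the *observed* division time of 21
minutes against the published 215-mcs figure, since they summarize the
source data, not this simulator.

## Membrane particles

Two independent particle species live on boundary sites (cell sites with
at least one 6-neighbour of different identifier): blue cortical force
generators (diffusion step 1 lattice length/mcs) and yellow Delta
molecules (step 2). Both are initialized by the shape-sensing rejection
rule: draw a random boundary site at distance `d1` from the center of
mass, draw a random lattice site at distance `d2` from the same center,
and place a particle at the boundary site iff `d1 > d2`. Acceptance is
proportional to the volume of the radius-`d1` ball, so per-site placement
frequency scales as `d1^3`, which loads membrane far from the center -
the spiky (+) side. Counts are fixed for the rest of the run (no
turnover). Particle counts are `round(conc x cell volume in sites)`; at
the fitted concentrations of 2.5-5.0e-2 per site this gives 105-209
particles per cell, matching the reported 80-160 per cell much better
than normalizing by boundary sites (31-62 on these shapes), which is why
cell-site normalization is the default (`conc_basis` switches it).

After every accepted copy the boundary moves; a particle stranded off the
boundary steps to one of the nearest boundary sites (uniform among ties,
searched in exact distance shells). At the end of each mcs every particle
makes one annulus hop; an empty annulus (or step 0) leaves it in place.

The division axis is the **cell vector**, the sum of unit vectors from
the center of mass to each blue particle. On an elongated cell the
shape-weighted blue particles load both poles, so the cell vector aligns
with the long axis (the long-axis rule emerges) and points toward the
heavier, (+), pole.

One measured property of this walk deserves a note: choosing uniformly
among in-annulus boundary sites is a degree-weighted random walk whose
stationary distribution is proportional to the local number of reachable
boundary sites. Where the boundary is locally dense - the tapered tip of
an eccentric cell - particles accumulate slowly (the uniform-initialized
share of the (+) side drifts from 0.500 to about 0.515 over 120 mcs).
This is intrinsic to the published movement rule on digitized thin
geometry, and it is the reason the diffusion-rate sweep is reported at
the early division time, where the artifact is negligible but the rate
ordering is weak (see Limitations).

## The fate switch

At division each daughter receives the yellow particles sitting on its
sites; the Delta activity is initialized to the daughter's share
`n / N_yellow` and Notch starts at zero. The two daughters then run a
Collier-type lateral-inhibition pair:

```
d(Not)/dt = F(Del_neighbour) - Not        F(x) = x^2 / (a + x^2)
d(Del)/dt = nu (G(Not) - Del)             G(x) = 1 / (1 + b x^2)
```

integrated with one fixed-step fourth-order Runge-Kutta step of `dt` per
mcs. The published system's parameter values are not reproduced in the
text, so the defaults `a = 0.01`, `b = 100`, `nu = 1`, `dt = 0.5` were
chosen by `verify_bistability()`: the V2b thresholds (Notch above 0.98
and Delta below 0.02) must be reachable, which requires `F(1) > 0.98`
(hence `a <= 0.02`) and `G(0.98) < 0.02` (hence large `b`), every initial
asymmetry from 0.01 upward must resolve with the majority daughter V2a,
and resolution from a 55:45 split takes ~26 mcs - "several tens" of
steps, comfortably inside the 500-mcs cap. The first daughter to cross
both thresholds is V2b and the other V2a; integration then stops. An
exactly tied split cannot resolve (the dynamics preserve symmetry) and is
broken by a seeded coin flip with a flag; so is the (never observed)
simultaneous crossing.

## Synthetic shapes

No segmented V2 volumes are distributed with the package, so the fixture
generator stands in for them. The family is a volume-preserving solid of
revolution, elongation 2.6 times the equivalent-sphere radius (a bipolar
progenitor shape), with a superellipse profile whose exponent is pushed
toward a cone on the (+) side (the process) and toward a blunt cap on the
(-) side (the body) by a single `taper` knob. Two properties motivated
this specific family, both implied by the reported experimental
outcomes:

- **Area balance.** Uniformly initialized Delta must produce no fate bias,
  so the boundary area on the two sides of the center-of-mass plane must
  be equal. The taper trades a long thin (+) end against a short wide
  (-) end at nearly constant half-area (measured 0.50 +/- 0.01 across
  the family).
- **Far-weighted (+) area.** The cubed-distance law must polarize, so the
  (+) half must hold its area at larger distances from the center of
  mass. Simpler families fail one constraint or the other: stretching one
  semi-axis of an ellipsoid unbalances the areas, while a thin radial
  spike maximizes the eccentricity index with so little boundary (and so
  large a center-of-mass shift) that the cubed-distance law yields no
  polarization at all.

The long axis is tilted off the voxel grid (direction `(1, 0.35, 0.21)`).
An axis-aligned shape's bounding-box extremes snap to whole voxel layers,
quantizing `A_long` in steps of about half a voxel over the radius
(~0.025 here); the oblique axis samples sub-voxel phases and makes the
taper-to-index map quasi-continuous, which is what `tune_to_target()`
needs to hit the six study eccentricities (0.002, 0.024, 0.031, 0.052,
0.063, 0.092) within 0.002. The tuner follows the smoothed trend of the
map (so taper stays monotone in the requested index) and fine-matches on
the local branch.

`make_synthetic_stack()` paints a linear intensity gradient along any
axis over a fixture, with optional Poisson noise and Gaussian blur, and
records the noiseless centroid offset so localization recovery can be
asserted exactly.

What the fixtures do *not* emulate: surface roughness and lumpiness of
real segmented cells, anisotropic voxels (real stacks are resampled to
the isotropic grid first), partial-volume intensity at the membrane, and
any correlation between eccentricity and volume. Passing ensembles on
these fixtures demonstrates the mechanism's behaviour on clean geometry
at matched eccentricities, not performance on raw microscopy.

## Ensembles and statistics

`run_division_ensemble()` runs seeded replicates per fixture - lattice
embedding, particle placement, rounding to the trigger, division,
partition, fate - and summarizes plus-side V2a / V2b counts, the bias
fraction, a chi-squared test against the 50:50 null (`sum((O - E)^2 / E)`
with the stated degrees of freedom, upper-tail p), and the angle between
the division axis and the original long axis. `sweep_fig4()` runs the
named perturbations: uniform yellow initialization, diffusion steps 0
and 4, and concentrations 5.0e-3 and 0.50 per site (concentration-to-
diffusion ratios 0.0025 and 0.25 against the baseline 0.025).
`fit_mode()` scores a candidate grid of (concentration, step) pairs
against a user-supplied target bias profile with 12 replicates per shape,
mirroring how the published operating point (5.0e-2 with step 1 for
orientation, 5.0e-2 with step 2 for fate) was selected; the target
profile is an argument because the experimental bias values are only
published as figure panels.

Default problem sizes, chosen so a full acceptance pass stays in the tens
of minutes on one core: 48 replicates per fixture for the baseline curve
and the sweeps, 144 for the uniform-initialization null (a null is
asserted as an absolute deviation, so it benefits most from averaging),
lattices of 56-66 sites per edge as dictated by the fixtures, and 1e5
draws for the distribution-law checks. A replicate takes a fraction of a
second; the published scale of 144 replicates everywhere is a flag away.

`calibrate_units()` converts the Monte Carlo clock through the observed
21-minute division time against the published 215-mcs average (~6 s per
mcs) and a diffusion step to physical units through the two-dimensional
relation `MSD = 4 D t` (step 2 on the 0.5-um lattice gives 4.2e-10
cm^2/s; step 1 gives 1.0e-10).

## Numerical and edge-case decisions

- Median filter borders replicate the nearest voxel, which makes the
  filter exact on constants and idempotent on coarse piecewise-constant
  volumes.
- Discriminant binarization scans the sorted unique values exactly
  (ties toward the smaller threshold); `"auto"` inversion makes the
  minority class the foreground so both staining polarities segment the
  object.
- Component labelling is breadth-first in scan order; size ties resolve
  to the component whose seed voxel comes first lexicographically.
- The ROC threshold maximizes Youden's J over observed values with the
  `>=` decision rule, ties toward the smaller threshold.
- A zero cell vector at division (possible when blue particles cancel)
  draws a uniformly random plane and flags the replicate; a cell that
  loses every boundary site aborts the replicate with a diagnostic.
- Blue particles exactly at the center of mass are excluded from the
  cell-vector sum (their direction is undefined) and counted.
- Fate integration is clipped at zero activity; the `max_mcs` budget
  left for the switch is the total cap minus the rounding steps already
  spent.

## Known limitations

- The face-counted surface is a weak shape discriminator for smooth
  digitized cells (it measures axis projections), so the division
  trigger acts as a rounding-progress clock only while the cell sheds
  its initial surface excess; sphericity progress is asserted on the
  inertia eigenvalue ratio instead.
- The annulus walk's degree-weighted stationary distribution (see above)
  slowly concentrates particles at thin tips. At the default division
  time this contributes less than 0.005 to the (+) share, but it
  prevents any single operating point from showing both a clean
  frozen-vs-baseline diffusion ordering and a clean uniform-
  initialization null: the frozen condition lacks the slight
  concentration the mobile conditions gain, so its bias can sit at or
  below the baseline's.
- Daughters are not re-rounded after division and multi-cell tissue
  context is out of scope; the two daughters interact only through the
  fate equations.
- Digitization granularity at 0.5-um voxels limits fixture tuning to
  about +/-0.002 in `A_long` and adds comparable noise to per-fixture
  polarization, visible as non-monotone wiggles in the bias curve at
  adjacent eccentricities.
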