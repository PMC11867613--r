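---
title: "Creeping-flow simulation of periderm-dwelling polyp pumping: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Creeping-flow simulation of periderm-dwelling polyp pumping: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

polypflow simulates how a millimetre-scale sessile polyp, living inside a
rigid pagoda-shaped periderm partly inserted into the sediment, exchanges
water with its surroundings by rhythmically expanding and contracting its
bowl-shaped subumbrella. At this scale (body ~2 mm, stroke periods of
seconds, speeds well below 1 cm/s) the Reynolds number is below one:
viscous forces dominate, inertia is negligible, and the flow at every
instant is fully determined by the instantaneous boundary motion. Each
snapshot of the cycle is therefore an independent stationary Stokes
problem — the quasi-steady creeping-flow regime.

The pipeline answers three questions about such a suspension feeder:

1. how fast is the water drawn through and above the peridermal aperture,
   and how quickly does that influence decay with height (the reach of its
   feeding current);
2. how does the flow depend on the expansion:contraction duty cycle
   (1 s:1 s up to 4 s:1 s, contraction fixed at 1 s);
3. what vorticity structures develop around the periderm over a cycle and
   in what order they form, touch the floor, and fade.

## Geometry: a parametric axisymmetric body

No digital model of the fossil is shipped; the `geometry` module *is* the
data generator. The periderm is a solid of revolution with a smooth
monotone taper from the basal radius (0.3 mm) to the aperture
(0.18 mm radius by default), optionally perturbed by sinusoidal annular
ridges (off by default, since ridge geometry is not quantified). Of the
2.0 mm total height, 0.18 mm is buried, leaving 1.82 mm exposed; the
domain floor is the sediment surface and the aperture plane sits at
z = 1.82 mm. The subumbrella is a bowl hanging apex-down inside the
periderm: zero radius at the apex (z = 1.12 mm), widest at the belly
(0.12 mm radius at 55% of its height), necking to the rim opening
(0.05 mm radius — the "mouth") at the aperture level. Both profiles are
single-valued radius-versus-height curves, exportable as two-column CSV.

Two printed dimensions of the original description conflict (a widest
diameter of 0.1 mm versus a characteristic opening of 0.003 mm used in a
Reynolds-number estimate, a factor 33 apart); both the belly radius and
the opening radius are therefore plain configuration parameters, and the
defaults above are one fixed, documented choice.

The tetraradial symmetry and the twelve apertural lobes of the real
organism are deliberately reduced to a body of revolution: the pagoda form
is near-axisymmetric, and the axisymmetric (r, z) reduction is what makes
a desk-scale, fully-resolved parameter sweep feasible. The 20 x 10 x 10 mm
cuboid domain becomes a cylinder of radius 5 mm and height 10 mm.

The solid region is everything between the (displaced) bowl wall and the
periderm flank — the calyx tissue fills that space, so the only fluid
route into the cavity is through the mouth. Internal anatomy (stalk,
manubrium, tentacles) is ignored.

## Kinematics: prescribed wall motion

The bowl wall moves radially only:
`r(z, t) = r0(z) + amplitude_scale * A(z) * s(t)`,
with zero axial and azimuthal surface velocity. `A(z)` is a natural cubic
spline through control points anchored to zero at the apex (the apex is a
fixed constraint); the default set — outward +0.05 mm at mid-bowl, inward
-0.02 mm at the rim — makes the belly inflate (drawing water in through
the mouth) while the mouth narrows toward full expansion, reproducing the
described mouth-minimum at the end of expansion.

`s(t)` rises 0 to 1 over the expansion phase and returns to 0 over the
contraction phase. Each phase's rate is a smooth bump with zero value and
slope at the phase endpoints, implemented as a Beta(4f+1, 4(1-f)+1)
density in normalised phase time so that the rate peak lands exactly at
fraction `f` of the phase. The defaults `f = 0.6` (expansion) and
`f = 0.5` (contraction) place the 3 s:1 s scenario's rate peaks at 1.8 s
and 3.5 s. The observed flow-speed peaks at the sampling stations sit
within a few hundredths of a second of these rate peaks: the speed equals
`rate x gain(shape)`, and the gain varies a few percent over the stroke as
the bowl inflates, which shifts the expansion-phase speed peak slightly
late (to about 1.86 s on the default grid) and the contraction peak
slightly early (about 3.48 s). This shift is a real property of the
quasi-steady model, not a numerical artefact.

### The amplitude scale

`amplitude_scale` multiplies the whole displacement field. Because the
original displacement table is not available, the scale had to be fixed
once. The natural calibration — matching the published 0.0155 m/s
expansion peak of the 1 s:1 s scenario at the z = 2.05 mm station — turns
out to be unreachable by about two orders of magnitude for *any*
admissible scale: the bowl can sweep at most a few hundredths of a mm^3
per phase inside the periderm, which caps the aperture volumetric rate
near 0.1 mm^3/s and hence the speed 0.23 mm above the ~0.2 mm-radius
aperture at the 1e-4 m/s scale. (Equivalently: an incompressible creeping
flow cannot move 40 times faster, 0.23 mm above the body, than any point
of its driving boundary; published boundary excursions bounded by the
periderm imply wall speeds below ~1 mm/s.) The default scale is therefore
frozen at 0.45, just inside the geometric admissibility limit of about
0.51 computed by `amplitude_scale_limit()` (bowl clear of the periderm by
the configured minimum clearance, rim open, profile non-negative, over
the whole cycle). All velocity outputs scale essentially linearly with
this parameter, so results for other choices can be read off directly.

## The flow solver

The `stokes` module solves, for one rasterized boundary state,

```
0 = -grad p + mu Lap u - (rho chi / eta) (u - u_s),    div u = 0
```

on a uniform staggered (MAC) grid in (r, z) with the axisymmetric metric
terms. `chi` is the solid indicator (cell-centre test, faces solid when
either neighbour cell is), and `u_s` the prescribed solid velocity —
Brinkman volume penalization with time scale `eta = 1e-8 s`, which pins
solid-face velocities to their targets to well below the 1% error
threshold. Boundary conditions: symmetry on the axis, no-slip floor, and
open (traction-free, reference pressure zero) top and lateral boundaries,
matching a hydrostatic far field.

Two implementation details matter for accuracy and robustness:

* **Wall-velocity extension.** The moving bowl wall is a stair-step set of
  penalized faces. Prescribing the surface speed directly there would make
  the driven volume flux depend on which stair faces the rasterization
  happens to produce. Instead the wall velocity is extended into the solid
  as the solenoidal field `u_r(r, z) = v_surf(z) r_s(z) / r`, whose flux
  through *any* surface at a given height equals the analytic swept-volume
  rate; the flux driven into the cavity is then rasterization-independent
  up to O(h) endcap effects. This is why the aperture flux balances the
  analytic cavity-volume rate to about 1% on the default grid (the
  conservation checks require 5%).
* **No incompressibility inside the body.** Cells inside the tissue are
  not fluid; imposing `div u = 0` there would be inconsistent with a
  deforming solid. The divergence constraint is assembled over fluid cells
  only, and the pressure is pinned to zero in solid cells.

Discretely, the volume-weighted momentum operator is symmetric positive
definite once the divergence constraint is handled, so the saddle-point
system is solved in SPD form by grad-div augmentation: factor
`K + gamma D' V D` once per snapshot with a sparse supernodal Cholesky
(CHOLMOD via Matrix), then iterate the augmented-Lagrangian (Uzawa)
multiplier update, each iteration costing only a pair of triangular
solves. With `gamma = 1e4 mu`, the discrete divergence reaches round-off
(~1e-13 of the natural `U/h` scale) in 4-8 iterations; the solver signals
non-convergence and excessive penalization error as errors rather than
warnings. During development the scheme was cross-checked against a
direct sparse-LU solve of the full saddle-point system; the two agree to
seven digits on the expanding-sphere oracle below. Stokes linearity and
reversibility hold bitwise because every step of the algebra is linear in
the right-hand side.

The analytic oracle for the solver is the radially expanding sphere,
whose creeping-flow field is the point-source field
`u = adot (a/r)^2`: a penalized sphere of radius 0.35 mm expanding at
0.01 m/s reproduces `adot/4` at `r = 2a` within 10% on the default cell
size.

## Pipeline and sampling

A scenario is one full cycle stepped at the snapshot cadence (default
0.05 s; the quasi-steady physics makes the cadence purely an output
choice, and peak times are refined afterwards by local 0.01 s sampling
around detected maxima). Each snapshot rebuilds the boundary state,
rasterizes, solves, and samples the ten axial stations
z = 2.05..2.50 mm (0.05 mm spacing) on the symmetry axis — "mouth flow
velocity" is operationalized as the speed at the z = 2.05 mm station,
the station nearest the aperture. Everything is deterministic; two runs
of one configuration produce byte-identical CSV exports.

On one CPU core a default-grid snapshot costs about 1.1 s
(120 x 240 cells, 41.7 um); the four canonical scenarios are ~280
snapshots (~5 min), and the grid-sensitivity rerun at the next sqrt(2)
refinement roughly doubles that scenario's cost. The test suite runs its
physics checks on a half-extent grid with the same cell size to stay
fast, and reserves the default grid for the acceptance checks.

## Derived quantities

* **Maximum-velocity tables** per cut point and scenario, tagged by phase
  (expansion / contraction / full cycle), with peak refinement.
* **Azimuthal vorticity** `omega_phi = du_r/dz - du_z/dr` by centred
  differences at cell centres, plus a nondimensional copy
  `omega* = omega_phi T_scale` (default `T_scale` = 1 s, the contraction
  duration).
* **Vortex chronology.** Detection mimics a saturated vorticity
  visualisation: connected same-signed regions of `|omega*|` above an
  absolute threshold (default 2e-4, chosen so that both dominant
  opposite-signed structures of the canonical 3:1 run are detected over
  their full spatial development, including the secondary structure's
  descent along the periderm to the floor), cores at the region extrema,
  frame-to-frame linking by core proximity and sign. Events: formation;
  floor contact; separation, defined as loss of wall contact with the
  periderm flank — a structure previously within `delta` (two cells) of
  the flank either recedes beyond `delta` or fades below the detection
  threshold. The fading route matters: in quasi-steady creeping flow the
  whole field scales with the instantaneous stroke rate, so stroke-driven
  structures dissolve in place as a phase ends rather than advecting
  away (there is no vortex shedding at Re << 1). The |omega|-extremum of
  the main structure sits in the mouth-jet shear layer at an essentially
  fixed wall distance, which is why the event uses region contact rather
  than core distance. With the defaults, the canonical 3:1 chronology is:
  main structure forms at ~0.05 s near the aperture, the opposite-signed
  secondary forms along the flank at ~0.15 s and reaches the floor
  mid-expansion, the main structure peaks near 2 s and separates (by
  fading) at ~3.0 s, an opposite-signed aperture structure replaces it at
  ~3.05 s and separates at ~4.0 s, closing the cycle.
* **Reynolds number** `rho U L / mu` from the simulated peak speed and the
  configured opening diameter; the canonical runs sit far below 1,
  consistent with the creeping-flow model assumption.
* **Grid sensitivity.** The 3:1 scenario is rerun on a ladder of uniformly
  refined grids (factor sqrt(2) per level); for each consecutive pair the
  cut-point speeds are compared snapshot by snapshot and the relative
  differences averaged, excluding snapshots whose reference speeds are
  below 1% of the global maximum (the flow is exactly zero at the phase
  endpoints, where a relative difference is undefined). The default grid
  differs from the next refinement by about 6.4%, inside the 5-10%
  acceptance band used for the original mesh study.

## What the defaults do and do not demonstrate

The synthetic geometry and kinematics emulate the published study
conditions: dimensions, insertion depth, duty cycles, fluid properties,
sampling stations, and the qualitative motion (belly inflation with mouth
narrowing). They do not emulate the unavailable displacement table, the
tetraradial lobes, ambient currents, or elastic tissue mechanics (the motion is prescribed;
mesogleal elasticity is not solved). Consequences worth keeping in mind:

* Relative and structural results — duty-cycle ordering of the peaks,
  identical contraction-phase traces across scenarios, jet decay with
  height, the vortex event sequence, grid convergence — are robust
  statements about the model class and transfer to any amplitude choice
  by Stokes linearity.
* Absolute speeds are tied to the frozen amplitude scale and sit near
  1e-4 m/s at the first station, about two orders below the published
  0.005-0.0155 m/s bracket, which the admissibility analysis above shows
  cannot be reached by any wall motion confined to the periderm. The
  published absolute values appear internally inconsistent with the
  published geometry; this package's numbers are the self-consistent
  counterpart under the documented reconstruction.
* Expansion-phase peaks scale exactly as `1/T_exp` across scenarios here
  (the shape path is identical, time merely stretches), so the simulated
  4:1 / 1:1 peak ratio is 0.25, whereas the published bracket implies
  ~0.32; the difference is within the spread expected from the unknown
  displacement programme.

## Numerical choices and degenerate inputs

* Rasterization requires the rim opening to span at least ~0.8 cells and
  the bowl-periderm gap at least ~1.2 cells; thinner features raise an
  under-resolved-geometry error instead of silently sealing the mouth.
* Boundary states that cross the periderm, close the mouth below
  `min_opening`, or drive the profile negative are rejected at
  construction (`displaced_surface`), not discovered downstream.
* The rest state (zero boundary motion) short-circuits to the exact zero
  field.
* Peak fractions of the temporal ramp are restricted to (0.25, 0.75),
  where the Beta-bump construction stays C1 with interior peaks.
* Cut points falling inside the solid body are rejected at sampling.
* Pressure is reported up to the open-boundary gauge (reference 0); it is
  a diagnostic, not used by any derived quantity.

## Known limitations

* One-way coupling only: the fluid does not push back on the tissue, and
  the periderm is perfectly rigid.
* The stair-step (first-order) boundary representation limits pointwise
  near-wall accuracy; flux-controlled quantities (the cut-point speeds)
  converge much faster than wall shear does.
* Axisymmetry cannot represent lobe-scale azimuthal structure around the
  aperture.
* Event *times* from the vortex tracker depend mildly on the detection
  threshold (the event *sequence* does not, over the two decades of
  threshold explored during development).
* The hydrostatic far field means no ambient-current interaction; the
  open-boundary condition is a zero-traction approximation appropriate
  when the boundaries are many body lengths away, as here.
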