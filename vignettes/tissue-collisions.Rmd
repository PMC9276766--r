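---
title: "Colliding epithelia: the front model, the boundary mechanics, and how tissellate computes them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colliding epithelia: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissellate)
```

## The model

`tissellate` rests on two experimental regularities of expanding epithelial
monolayers:

1. **Uniform normal expansion.** A freely growing epithelium advances its
   edge outward at a normal speed $v_n$ that is uniform along the perimeter
   and independent of tissue geometry or density, except in zones of very
   high curvature. For MDCK monolayers $v_n \approx 29.5\ \mu m/h$, which is
   the package default.
2. **Pinning.** When two tissue fronts meet they stop *as fronts*: the
   contact line does not advance further by migration, and the tissues do not
   mix. Any later boundary displacement is a mechanical effect (below), not
   front propagation.

Together these make the healed shape of any arrangement of tissues a
parameter-free geometric prediction: a point $x$ belongs to the tissue whose
front reaches it first, with arrival time $T_k(x) = d_k(x)/v_k$, where
$d_k$ is the (geodesic, obstacle-respecting) distance from seed $k$. For
convex seeds and equal speeds this reduces to the additively weighted Voronoi
partition computed in closed form by `arrival_partition()`; the general case
(unequal speeds, wrap-around, engulfment of a slow tissue by a fast one) is
handled by the stepped engine in `simulate()`.

### Boundary mechanics after contact

Far from the outer edges (where polarized traction is concentrated within
$\sim 50\ \mu m$ of the margin), the force balance at a collision boundary is
friction-dominated:

$$-\nabla P = \xi\, \boldsymbol v, \qquad
  \boldsymbol v = -\frac{P'(\rho)}{\xi} \nabla \rho ,$$

with $\xi$ the cell–substrate friction coefficient (assumed
density-independent) and $P(\rho)$ a monotone equation of state. The boundary
therefore moves from high to low cell density at a speed proportional to the
local density gradient. Fitting a line through measured
(gradient, boundary-velocity) pairs gives the pressure–density slope
$P' = -\mathrm{slope}\cdot\xi/3600$ (the 3600 converts the measured
$\mu m/h$ to the $\mu m/s$ of the force balance). Adopting the logarithmic
equation of state $P(\rho) = K \ln(\rho/\rho_e)$, whose slope is
$P'(\rho) = K/\rho$, converts the fitted $P'$ into a bulk modulus
$K = P'\rho$ at the working density. `eos_pressure()`, `bulk_modulus()` and
`stiffness_from_tension()` implement these conversions;
`fit_pressure_slope()` returns the whole chain as a `mech_fit` object.

Two conventions deserve flagging. The line is fitted through **assay-average
points** (each assay type contributes one summary point), while the
correlation coefficient $r$ is reported over the individual pairs — both
behaviours are exposed. And whether the canonical fit is constrained through
the origin is genuinely ambiguous; `fit_pressure_slope()` is unconstrained by
default with a `through_origin` option.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `v_n` (default_speed) | μm/h | 29.5 | measured MDCK free-edge speed |
| grid spacing | μm/px | 10 | resolves boundaries finer than a PIV window |
| `dt` | h | 1/3 | 20-min imaging cadence; must satisfy $v\,dt \le$ spacing |
| PIV window | μm | 88 | typical final PIV window size |
| kymograph `band_margin` | μm | 1000 | excludes edge effects at tissue top/bottom |
| time smoothing | timepoints | 3 | standard moving average of PIV data |
| stall `threshold` | μm/h | 3 | center-of-expansion detection level |
| gradient `width` | μm | 300 | side regions immediately left/right of boundary |
| velocity `window` | h | 20–36 | after collision, before the boundary stalls |
| `xi` | Pa·s/μm² | 100 | literature-scale cell–substrate friction |

## Numerical design of the front engine

The continuum rule says nothing about discretization, so the scheme is this
package's own choice, validated against analytic boundary conics and the
free-circle speed calibration:

* **Competitive geodesic growth.** Each tissue carries a continuous advance
  budget $R_k(t) = v_k t$ (sub-pixel remainders are never discarded, so
  long-run edge speeds are exact) and a per-pixel geodesic
  distance-from-seed field $G_k$, grown incrementally by shortest-path
  relaxation: a free pixel becomes claimable when
  $\min_p [G_k(p) + \lVert x - p \rVert] \le R_k$, minimized over already
  claimed pixels $p$ within a $9\times9$ window.
* **Isotropy.** Hops use exact Euclidean lengths over all 48 primitive
  lattice offsets with $|di|,|dj|\le 4$ (maximum angular gap $14^\circ$,
  worst-direction metric excess $\approx 0.7\%$, direction-averaged
  $\approx 0.2\%$). Naive per-step binary dilation (one pixel per step)
  would grow Manhattan diamonds and underestimate radial speeds by tens of
  percent; the geodesic-relaxation scheme keeps fronts circular.
* **Raster registration.** Seed boundary pixels start with
  $G = -\mathrm{spacing}/2$, because a boundary pixel's *center* sits about
  half a pixel inside the continuum front. This removes a constant half-pixel
  start-up lag; it does not affect speeds.
* **Tie-breaks.** A pixel reachable by several tissues in one step goes to
  the smallest continuous arrival estimate $G_k/v_k$; exact ties go to the
  lower tissue id. Deterministic, so identical inputs give bit-identical
  movies.
* **CFL condition.** `step_fronts()` refuses $\max_k v_k\,dt >$ spacing;
  with the defaults (29.5 μm/h, 10 μm, 20 min) the advance per step is just
  under one pixel.
* **Known limits.** Hops of length up to 4 pixels can tunnel through another
  tissue's wall if that wall is thinner than ~3 pixels — keep features
  thicker than ~4 pixels (or refine the grid). High-curvature zones get no
  correction (the uniform-$v_n$ assumption itself degrades there), and the
  engine is a continuum model: sub-100-μm multi-tissue features such as
  tri-collision escape streams are outside its validity domain and are
  deliberately not simulated; only tri-junction geometry extraction
  (`find_trijunctions()`) is provided.

`arrival_partition()` is computed independently (exact Euclidean distance
transforms via `EBImage::distmap`), which is what lets the test suite use it
as an oracle against `simulate()` rather than re-deriving one from the other.

## Operational definitions

* **Boundary curves** are midpoints of 4-adjacent pixel pairs of the two
  labels, chained by nearest-neighbour traversal — a sub-pixel polyline.
* **Roughness** is the RMS deviation of the boundary's transverse coordinate
  about its mean line after arc-length resampling at 10 μm. The community
  does not share a single canonical roughness metric; RMS transverse
  deviation is the standard interface-roughness choice and supports relative
  ("twice as smooth") comparisons. Curves that double back are still
  measured, with a `multivalued` flag.
* **Prediction error** is the symmetrized mean nearest-vertex distance
  between two curves.
* **Fusion time/location** are taken from the first frame in which the two
  labels are 4-adjacent; descriptions of the "initial point of the boundary
  line" do not pin down a finer convention.
* **Density gradients** use fractional window coverage of the two 300-μm side
  regions, making the estimate exact for linear profiles whenever regions
  align with window edges and accurate to well under 1% otherwise.
* **Dye segmentation** normalizes each channel to its 1st–99th percentile
  range inside the tissue mask before per-pixel comparison, with ties to the
  first channel. Histogram "normalization" is underspecified in common
  protocol descriptions; percentile matching is robust to the edge dimming
  that motivates normalizing in the first place, and the choice is flagged
  here deliberately.

## The synthetic-data generator

`synth_collision()` emulates a two-rectangle collision assay in 1D along the
collision axis (replicated across y with independent noise):

* Pre-collision, each tissue's velocity profile is linear and divergent about
  its centroid, reaching $\pm v_n$ at the edges — so the tissue dilutes
  uniformly as it spreads while density also grows logistically
  (0.035 /h toward 6000 cells/mm² by default; larger tissues are denser at
  collision, as observed).
* Post-collision, the boundary moves by the pressure-driven flow relation
  evaluated on the generator's *own* density profile using the same
  operational 300-μm two-window gradient the analysis uses (reimplemented
  independently of the analysis code). The velocity field is piecewise
  linear and divergent about a center of expansion that relaxes
  exponentially (default 12 h) from the denser/wider tissue's centroid to
  the fused centroid, passes through $v_b$ at the boundary (the boundary is
  a material point), and is clipped to $\pm v_n$ at the outer edges.
* Density evolves by conservative upwind finite volumes (fine grid 10 μm,
  substeps chosen for advection Courant ≤ 0.5 and diffusion number ≤ 0.4)
  plus optional lateral diffusion (default 2000 μm²/h). How fast real
  boundary gradients dissipate is not firmly established, so the relaxation
  is an exposed parameter rather than an assertion. With growth, diffusion
  and noise off, the emitted window fields satisfy the 1D continuity
  equation to discretization error — a property the test suite checks.
* Noise: additive Gaussian 2 μm/h per velocity window (below the 3 μm/h
  stall threshold, the scale PIV noise must have for that threshold to be
  usable) and multiplicative 8% per density window (comparable to
  nuclei-counting noise after band averaging). Nuclei are an inhomogeneous
  Poisson pattern matching the noiseless density field.
* Study conditions follow the collision assays the generator emulates:
  1000-μm-wide, 3000-μm-tall rectangles with a 500-μm gap, seeding densities
  2600 vs 1800 cells/mm² for the density-mismatch preset.

All randomness flows through R's default Mersenne-Twister generator via a
single `seed` argument; a fixed seed gives bit-identical outputs, and seeds
are recorded in the returned ground truth.

What the generator does **not** emulate: 2D flow structure (fingering,
swirls), cell-scale granularity, heterotypic mechanics, escape streams, or
image-level content (no phase contrast or fluorescence rendering). Passing
the end-to-end recovery tests therefore shows the *pipeline* is consistent
and unbiased under the stated noise model — not that real tissues obey the
model; that case is made by the experiments the model descends from.

## Problem sizes used by the tests

The shipped tests run simulations on worlds of roughly 1.8–3.6 mm at 10 μm
spacing for 10–50 h of model time, five-assay synthetic recovery studies at
default noise, and 25-pair slope-recovery draws — sizes chosen so the whole
suite completes in about a minute on one core while still exercising every
code path at experimentally realistic scales. The acceptance script uses the
calibration geometry itself (a free circle of initial radius 500 μm over
10 h) and the default mechanics parameters.

## Known limitations

* The engine predicts shapes; it does not feed post-collision boundary drift
  back into the tessellation geometry (shape prediction and boundary
  mechanics are treated as separate phenomena, as in the source assays).
* `arrival_partition()` is exact only for convex seeds and equal speeds; it
  warns on non-convex seeds and remains a qualitative oracle under strong
  speed mismatch.
* Label TIFF metadata lives in a `.meta` YAML sidecar (the installed `tiff`
  writer does not expose the ImageDescription tag); pixels remain readable
  by any TIFF reader.
* Friction is density-independent and the equation of state logarithmic by
  assumption; density-dependent $\xi$ or general $K(\rho)$ are out of scope.
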