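---
title: "Sequential vascular tracing: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential vascular tracing: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesseltrace)
```

## The model

`vesseltrace` builds a connected vascular segmentation by *sequential local
segmentation*. The premise: viewed through a cube roughly five radii wide
and centered on a vessel, vasculature of very different sizes and anatomical
regions looks alike — a bright tube crossing the cube, sometimes splitting.
A segmenter trained (or engineered) for that local problem generalizes far
better than a whole-volume model, and stringing local predictions together
along the vessel guarantees the connectivity that downstream flow simulation
requires.

One tracing iteration, starting at point `p_i` with unit tangent `t_i` and
radius estimate `r_i`:

1. **Subvolume.** Cut the axis-aligned cube of side `L = m (r_i + r_{i-1})/2`
   (default multiplier `m = 5`) centered at `p_i`. Carrying the previous
   radius protects against a single underestimate collapsing the cube. If
   more than `gamma*` of the voxels are predicted vessel, the cube is too
   small relative to the vessel; enlarge by `enlarge_factor` and re-segment,
   up to `max_enlargements` times.
2. **Local segmentation.** Any function `image_volume -> seg_map` on the
   same grid with values in [0, 1] satisfies the segmenter contract. The
   shipped `oracle_segmenter()` applies optional Gaussian denoising and a
   logistic squashing of `(intensity - threshold)/scale`; trained CNNs plug
   in behind `get_segmenter("module:pkg::fun")`.
3. **Surface and caps.** The 0.5 iso-surface is extracted in physical
   coordinates; where the vessel crosses a cube face the surface is open,
   and each open boundary loop is a truncation boundary ("cap") with a
   center. The cap nearest the previous stepping point is the source; the
   rest are targets. Fewer than two caps means the cube saw no through-going
   vessel — a failure handled by the chances mechanism.
4. **Centerline.** The speed field `F` is the Euclidean distance to the
   vessel wall (plus a small floor) inside the binarized prediction, zero
   outside. Fast marching solves `|grad T| F = 1` from the source; gradient
   descent on `T` from each target then yields one centered polyline per
   target, with per-point radii read from the distance transform.
5. **Stepping and bifurcations.** The stepping point is at 80%
   (`step_fraction`) of each branch's arclength from the source. The
   largest-radius branch continues; the others are queued with their point,
   tangent and radius. The queue is kept sorted by radius (largest first) so
   main vessels are traced before their daughters.
6. **Chances.** On a local failure (empty segmentation, missing outlet,
   unreachable target, stalled descent) the tracer advances one radius along
   the current tangent, `p <- p + R t`, and retries — at most `max_chances =
   3` consecutive times; the counter resets on success. This carries the
   trace across locally ambiguous image regions.
7. **Assembly.** Every non-empty local prediction is fused into a global
   accumulator as a Gaussian-weighted mean: weight `w = exp(-d^2/sigma^2)`
   with `sigma = L/4` of the contributing cube, so a cube-face voxel
   (`d = 2 sigma`) contributes with weight `exp(-4) ~ 0.02`. Predictions are
   least reliable near cube borders; the weighting encodes exactly that.
   Finalization thresholds the fused map at `t = 0.5`, keeps the largest
   26-connected body, extracts the global surface and smooths it.

Branches end at the image boundary (the next cube would request data that
does not exist), below `R_min`, after exhausted chances, or when the region
was already traced; the trace ends when the queue is empty, after `N_max`
total steps, or `NB_max` branches.

### Assumptions

* Vessels are locally tubular and brighter (after normalization) than their
  surroundings; the local segmenter is the only component that ever
  interprets intensities.
* The image grid is axis-aligned with positive spacings; oblique direction
  matrices are rejected at the IO layer rather than silently mishandled.
* One seed traces one connected tree. Loops in the vasculature are handled
  only in the sense that retracing prevention terminates a branch that
  re-enters fused territory.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `size_multiplier` | 5 | – | cube side per unit mean radius |
| `gamma_star` | 0.5 | fraction | vessel-fraction cutoff triggering enlargement |
| `enlarge_factor`, `max_enlargements` | 1.25, 4 | – | bounded geometric cube growth |
| `step_fraction` | 0.8 | fraction | arclength position of the next step |
| `max_chances` | 3 | – | consecutive failure retries per branch |
| `n_max` | 500 | steps | global step budget |
| `r_min` | 0.5 | mm | minimum radius to keep tracing a branch |
| `nb_max` | 15 | branches | branch budget |
| `retrace_check_period` | 5 | steps | cadence of the retracing check |
| `retrace_overlap` | 0.9 | fraction | coverage that counts as "already traced" |
| `retrace_buffer_steps` | 3 | steps | current-branch contributions ignored by the check |
| `sigma_fraction` | 1/4 | of `L` | fusion weight width |
| `threshold` | 0.5 | – | fused-map binarization (`>=` keeps) |
| `smooth_iterations`, `passband` | 10, 0.01 | – | mesh smoothing schedule |
| sampler `mu_r`, `var_r` | 5, 1 | – | side-length multiplier law `alpha ~ N` |
| sampler `mu_s`, `var_s` | 0, 0.8 | – | in-plane shift law `beta ~ N` |

`gamma_star = 0.5` sits between the fill fraction of a well-sized cube
(a tube of radius `r` in a cube of side `5r` fills about `pi r^2 L / L^3 ~
0.13`) and that of a cube no wider than the vessel (`pi/4 ~ 0.79`), so it
cleanly separates "vessel dominates the cube" from normal operation.
`enlarge_factor`/`max_enlargements` bound the growth geometrically (at most
`1.25^4 ~ 2.4x`); unbounded growth on a degenerate segmenter would never
terminate. The retracing values are conservative: checks run every 5 steps,
require 90% coverage both at the current point and one look-ahead point
(see below), and ignore the current branch's three most recent
contributions so a branch never trips over its own trail.

## What the phantom generator emulates — and what it does not

`make_phantom()` renders trees of capsules (cylinders with hemispherical
ends, so parent–child junctions are watertight) on a voxel grid: a voxel is
foreground iff its center lies inside some capsule. The image is two-level
intensity, Gaussian-blurred (`blur_sigma`, mm) and corrupted with additive
Gaussian noise — the minimal model reproducing the *blurred, ambiguous
boundary* failure mode that makes local vessel segmentation hard. Ground
truth (mask and axis centerlines with per-branch radii) is exact by
construction, which is what makes every downstream stage testable without
external data.

The standard suite (`make_standard_suite()`) fixes five geometries at 0.5
mm spacing, blur 0.5 mm, noise sigma 0.05: a straight tube, a 90-degree
bend, a symmetric Y-bifurcation, an asymmetric tree with a 3:1 side branch,
and a tube tapering below the 0.5 mm `r_min`. Margins are anisotropic by
design: transverse margins leave room for five-radii cubes, while a small
margin along a vessel's axis places the vessel end at the volume face so
boundary termination is actually exercised. These are the package's study
conditions; the suite seeds are fixed so every run is reproducible.

Not emulated: CT/MR physics (beam hardening, bias fields, contrast bolus
dynamics), pathology (aneurysms, stenoses, calcifications), curved
tapering within a single branch, touching-but-unconnected vessels, and
anisotropic point-spread functions. Tests passing on phantoms therefore
demonstrate the *mechanics* of the tracer — stepping, bifurcation handling,
stop criteria, fusion, metrics — not clinical segmentation accuracy, which
is entirely a property of the plugged-in segmenter.

## Numerical choices

**Iso-surfacing.** Surfaces are extracted by marching over the Kuhn
6-tetrahedra decomposition of each grid cell with linear interpolation
along edges. The decomposition tiles space consistently across cell faces,
has no ambiguous configurations, and needs no 256-case tables; the price is
more (smaller) triangles than classic cube-table marching. On hard binary
input any iso-surfacer returns a staircase whose area overstates a smooth
surface's by tens of percent; the pipeline's smoothing pass removes this,
and the tests assert near-analytic sphere area both for a one-voxel
anti-aliased field and for a binary ball after the standard smoothing
schedule.

**Eikonal solver.** Fast marching uses second-order one-sided upwind
differences wherever two accepted neighbours line up along an axis, and
initializes a 3-voxel ball around the source with the exact local solution.
Both refinements target the well-known point-source error of first-order
marching, which otherwise reaches several percent of the travel time and
would dominate centerline placement in short subvolumes. The test suite
cross-checks the solver against an independent 26-neighbour Dijkstra oracle
on random blob masks, with edge weights integrating the slowness `1/F` by
the log-mean (exact for the piecewise-linear distance-transform speed).
Agreement is asserted as a per-mask *mean* relative difference below 5%:
the graph metric itself overestimates Euclidean travel times by up to ~8%
in unfavourable directions, so voxel-wise coincidence with Dijkstra is not
a property a correct solver should have.

**Centerline descent.** Descent on `T` uses sub-voxel steps of
0.25 x (minimum spacing) along the trilinearly interpolated gradient, and
falls back to discrete steepest descent on the voxel lattice whenever the
interpolated step stops reducing `T` (thin, one-voxel channels; plateaus).
The discrete fallback strictly decreases `T`, so termination at the source
is guaranteed wherever the target is reachable. Targets that are
unreachable (disconnected prediction) or stall are dropped individually;
the step fails only if *every* target fails — otherwise one marginal
daughter would abort the main vessel's continuation.

**Radius convention.** The distance transform measures to the nearest
*background voxel center*; the 0.5 iso-surface sits about half a voxel
closer. Reported radii therefore subtract half the minimum spacing. Without
this correction a one-voxel-wide vessel reports `r ~ spacing` and the
`r_min` stop criterion can never fire on tapering vessels.

**Fusion arithmetic.** The fused value is the true weighted mean
`sum(w s) / sum(w)`. The weight exponent uses the squared distance,
`w = exp(-d^2/sigma^2)`: that is the form under which the stated boundary
weight (`~0.02` at `d = 2 sigma`) holds, and the only dimensionless one.
Both choices make constant predictions fuse to the same constant — an
invariance the test suite enforces on randomized overlapping cubes.

**Loss conventions.** `cross_entropy()` returns the mean Bernoulli
log-likelihood (a non-positive number) and the batch loss *subtracts* it:
`L = sum(1 - D - CE)`. Perfect predictions give ~0; the ordering of the
loss landscape matches the conventional BCE-plus-Dice loss exactly, only
the offset differs. Probabilities are clamped to `[1e-7, 1 - 1e-7]` before
logs. Dice on two empty maps is defined as 1 so degenerate all-background
patches do not poison batch statistics.

**Patch sampler geometry.** The in-plane shift direction
`w = (a u + b v)/||a u + b v||`, `a, b ~ U[-1, 1]`, is *not* angle-uniform:
drawing from the square loads the diagonals of the (arbitrary) `u, v`
basis by up to 2:1. The law is kept as stated — the anisotropy is relative
to an arbitrary basis and immaterial for training-patch diversity — and
the test suite checks the empirical angle distribution against the
analytic density of this law (proportional to `1/max(|cos|, |sin|)^2`),
plus unit norm and exact orthogonality. Side multipliers are redrawn below
`alpha_min = 0.5` so cube sides stay positive (a ~`3e-6` truncation of the
`N(5,1)` law).

**Normalization.** CT foreground statistics (0.5/99.5% clip bounds, mean,
standard deviation) are pooled across training cases and held constant at
inference; per-case statistics would make inference depend on the test
image's annotation. MR z-scoring is per-image at application time.
Percentiles interpolate linearly between order statistics; standard
deviations use the population convention; a degenerate sigma is floored at
`1e-8` so constant patches normalize to zero rather than erroring.

**Mesh smoothing.** Taubin lambda/mu smoothing — the standard two-step
low-pass member of the windowed-sinc filter family — with `lambda = 0.5`
and `mu` from the passband relation `k_pb = 1/lambda + 1/mu`, run for 10
iterations at passband 0.01. Cut-plane (boundary) vertices are held fixed;
vertex count and connectivity are preserved.

## Design decisions that were genuinely open

* **Continuation tie-break.** The largest-radius outlet continues, but
  radius estimates carry noise: at a symmetric bifurcation seen in two
  consecutive subvolumes, pure radius ordering makes the tracer flip
  between daughters and then kill the orphaned half as "already traced".
  Radii within 20% of the largest are treated as tied and the candidate
  best aligned with the current direction of travel continues.
* **Queue deduplication.** A bifurcation detected in two consecutive cubes
  would be pushed twice; pushes within 2 local radii of an existing queue
  entry are dropped. Retracing prevention remains the backstop for
  duplicates that slip through.
* **Retracing look-ahead.** The periodic check requires 90% coverage both
  at the current point and at a point two radii ahead. A young side branch
  necessarily starts inside territory its parent's cubes already fused;
  the look-ahead lets it escape while still terminating genuine retraces
  and duplicate branches.
* **Chance accounting is per branch** (the counter resets on success and at
  every queue pop), so one difficult region cannot exhaust the allowance of
  an unrelated branch.
* **Partial cubes are rejected by default** (`max_outside_fraction = 0`):
  a cube that pokes outside the volume is the boundary stop criterion, not
  something to zero-pad away. The fraction is configurable for users who
  want lenient boundary behaviour.
* **First-step source disambiguation.** "Closest to the previous stepping
  point" is undefined at the seed; the tracer uses the virtual point
  `seed - R_0 * direction`, which orients the first step along the seed
  direction.

## Problem sizes

The shipped tests and phantoms run at desk scale by choice: suite volumes
are 40–60 mm a side at 0.5 mm spacing (~10^5–10^6 voxels), full traces take
one or two seconds, the sampler moment checks use 10^5 draws, and the
eikonal oracle comparison uses ten 20-cubed masks. All sizes scale with the
input; nothing in the implementation is specific to these dimensions.

## Known limitations

* Axis-aligned grids only; oblique NIfTI/MetaImage orientations are
  rejected, not resampled.
* The oracle segmenter is an intensity model: it is the reference
  implementation of the contract and the test vehicle, not a clinical
  segmenter. On real angiography a trained 3D U-Net (or similar) must be
  plugged in.
* One seed, one tree: multi-seed fusion and automatic seed detection are
  out of scope.
* Radius estimates are mask-derived and quantized at the voxel scale;
  sub-voxel vessels (below ~1.5 voxels diameter) segment unreliably and
  terminate via `r_min` or chance exhaustion — by design, mirroring the
  resolution limit of the imaging.
* The retracing heuristics (period, coverage fraction, buffer, look-ahead)
  are declared defaults exposed in `tracer_config()`; they were chosen
  conservatively and are not adaptive.
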