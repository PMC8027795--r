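---
title: "Methods: 3D muscle morphometry with musclemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D muscle morphometry with musclemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclemorph)
```

This vignette is the package's own account of its methods: what each
stage computes, the conventions and parameters it relies on, what the
synthetic-data generator does and does not emulate, and the design
choices made where more than one defensible option existed.

## Coordinate and unit conventions

All volumes are arrays ordered `(z, y, x)` with physical voxel sizes
`(dz, dy, dx)` in micrometres. Voxel centres sit at integer indices and
the physical coordinate of index `i` (1-based in R) is `(i - 1) *
voxel_size`. The fibre axis of all synthetic muscle is `+x`. Using one
convention everywhere — and testing it everywhere — is the single most
important guard against axis bugs in anisotropic 3D work, where z-steps
are typically 2–8 times the in-plane pitch.

A consequence worth stating: object volume is defined as `voxel_count
* dz * dy * dx`, so a 100-slice, 704 × 704-pixel stack at 10 nm pixels
and 30 nm steps has a physical volume of `r
round(physical_volume(grid_spec(c(100, 704, 704), c(0.03, 0.01, 0.01))),
1)` µm³.

## Segmentation chain

The classical chain is: Gaussian prefilter → per-slice background
subtraction → Otsu threshold → distance-transform watershed →
3D connected-component labelling → size and border filter.

**Gaussian prefilter.** `gaussian_sigma` (default 2) is interpreted as
the in-plane standard deviation in pixels; the z-sigma is scaled by
`dy/dz` so the smoothing is isotropic in physical units. On noisy data
the filter suppresses spurious Otsu foreground; on noise-free synthetic
data it only widens edges, which is why the recovery tests run it at 0.

**Background correction.** The method is deliberately minimal: per-slice
median subtraction clipped at zero. It is deterministic, parameter-free
and adequate for synthetic backgrounds; it can be switched off.

**Per-slice Otsu.** `threshold_stack(x, "per_slice")` computes an
independent Otsu threshold (256 levels over the slice's own intensity
range, via EBImage) on every z-plane. Re-estimating the threshold per
plane compensates for the monotone intensity loss with imaging depth:
on a depth-decayed stack a single global threshold drops the deep
foreground, while the per-slice variant stays on target (this is pinned
quantitatively in the tests as foreground Jaccard ≥ 0.99 versus < 0.99).
A constant slice has no Otsu threshold; it becomes background and emits
a classed warning rather than an error, because empty planes are normal
at stack margins.

**Watershed splitting.** Touching organelles are split on the Euclidean
distance transform of the mask, computed with anisotropy-aware physical
spacing (a separable parabolic-envelope transform in compiled code).
Seeds are the regional maxima that survive h-maxima suppression at
depth `watershed_h` (µm of distance height, default 0.2): maxima
shallower than `watershed_h` merge into their neighbours, deeper ones
seed separate objects. Flooding proceeds from the seeds in order of
decreasing distance; every foreground voxel receives exactly one label,
so the watershed conserves foreground voxel counts. The default is
biased towards over-splitting rather than leaving large fused objects;
consequently genuine inter-mitochondrial connections can be cut — a
known compromise of any automated splitting rule. The parameter is a
physical length, so it transfers across voxel geometries.

**Labelling and filtering.** Components are labelled at 26-connectivity
by default (diagonal contacts across z-slices connect); relabelling an
already-labelled volume only refines (splits disconnected parts of one
label), never merges, so watershed cuts survive. The size filter keeps
objects with at least `min_voxels` voxels (default 100; an object of
exactly 100 voxels survives — "min N" is read as N being admissible).
Size filtering runs before border exclusion and both removal counts are
logged in the provenance; the order is a fixed convention so runs are
replayable. Border exclusion removes objects owning any voxel on any of
the six stack faces, since their morphometry would be truncated.

## Morphometry

For each object the covariance matrix of voxel-centre coordinates in
physical units is eigen-decomposed; the moment-equivalent solid
ellipsoid has full axis lengths `2 * sqrt(5 * lambda)` (a solid
ellipsoid of semi-axis `a` has second moment `a²/5`). No within-voxel
correction term is added; at ≥ 20 voxels per axis the discretisation
error of axes and volume is below 5 %, which the tests enforce.

Degenerate cases: eigenvalues are floored at `(min(voxel_size)/2)² / 5`
so coplanar or collinear voxel sets never report zero thickness or
infinite flatness; a single-voxel object reports its voxel dimensions,
sorted descending, as axes.

Orientation: eigenvectors are sign-ambiguous, so the long axis is
folded to make the azimuth (angle to `+x` in the xy-plane) lie in
[0°, 90°]; elevation is folded likewise. Near-isotropic objects
(relative eigenvalue spread below 1 %) report azimuth and elevation 0
by a tie rule — for a true sphere the direction is meaningless and any
reported angle would be rasterisation noise.

Shape classes use the strict inequalities exactly as defined:
sphere iff elongation < 1.3 **and** flatness < 1.3; rod iff
elongation > 2.5; ellipsoid otherwise, including values exactly on a
boundary. Boundary inputs are measure-zero in practice but the
behaviour is pinned by tests.

## Cross-striation index

The index scores lateral M-band registration across a field of
parallel myofibrils. From a start M-band on the first myofibril, the
path steps to the Euclidean-nearest M-band of each successive
myofibril; the index is the perpendicular first-to-last lateral span
divided by the path length, hence exactly 1 for perfect registration
and < 1 otherwise (the path can never be shorter than the
perpendicular). Nearest-candidate ties are broken towards the candidate
closer to the start M-band's axial coordinate, then towards the smaller
coordinate — an arbitrary but deterministic rule, chosen so replays are
exact. When several start M-bands are evaluated (the default is all
M-bands of the first myofibril), their indices are averaged; the same
averaging is used to collapse multiple fields per animal
(`aggregate_per_animal()`), so each animal contributes one value.

Two closed-form configurations anchor the implementation: two
myofibrils 10 µm apart with single M-bands 5 µm out of register give
`10 / sqrt(125) ≈ 0.8944`, and three myofibrils with the middle one
offset by 5 µm give `20 / (2 sqrt(125))`, the same value.

M-band detection on images is intentionally simple, because synthetic
fibres are straight: myofibrils are lateral peaks of the z- and
x-averaged intensity, M-bands are axial peaks along each myofibril with
a minimum separation of half the dominant period, and the dominant
period itself comes from the first non-zero-lag autocorrelation maximum
with parabolic sub-sample refinement (`sarcomere_period()`). Profiles
without periodic structure return `NA` with a classed warning. Curved
or branching myofibrils are out of scope.

## Content quantification

Channel content is reported as thresholded area (per-slice Otsu), not
integrated intensity, which makes the mitochondria-to-actin ratio
invariant to any positive rescaling of either channel's intensities.

For tubular fibres the stack is resliced so the tube's long axis
becomes the stacking axis: output slices are the old `(z, x)` planes
stacked along the old `y`, with the old z axis linearly interpolated
onto the x pixel pitch so cross-sections are isotropic in-plane (an
isotropic input reslices as an exact transpose). Per cross-section the
peripheral region is the actin-positive annulus after a morphological
closing (disc radius 3 px by default, to seal small threshold gaps);
the central region is the hole it encloses, found by filling the
annulus and subtracting it — equivalent to a border flood fill, and
parameter-free. Slices without a closed annulus are flagged and
excluded; if no slice has one, the report carries `NA` fractions and a
classed warning. Whether the boundary should be the annulus inner edge
or some fixed-radius circle is a genuine modelling choice; the annulus
rule was chosen because it needs no manual input and matches how the
regions are drawn on cross-sections in practice.

## Synthetic data: what it emulates, and what it does not

The generator produces the three architectures the pipeline targets,
with exact ground truth:

- **Ellipsoid populations** (`make_mitochondria_volume`): solid
  ellipsoids rasterised by the voxel-centre-inside rule, placed by
  rejection sampling with bounding-sphere separation; overlap is
  impossible by construction, and a shortfall is reported as a classed
  warning, never silently. Defaults emulate flight-muscle mitochondria:
  20 % near-spheres, 60 % ellipsoids, 20 % rods, semi-axes chosen to
  give volumes of roughly 1–4 µm³, long axes tilted around the fibre
  axis with a 15° spread. The angular spread is a free parameter — no
  measured orientation distribution was available to copy, so the
  default is a plausibility choice, stated once.
- **Striation patterns** (`make_striation_pattern`): parallel rods with
  Gaussian-profile M-band intensity maxima every `sarcomere_length`
  (default 3.2 µm, a typical relaxed sarcomere length for adult fly
  muscle). Cross-striated layouts share one axial phase, fibrillar
  layouts draw independent phases, and every M-band is jittered axially
  by `N(0, registration_jitter)`. Over 30 fields per level, the mean
  index decreases strictly through jitter levels {0, 0.1, 0.25, 0.5} ×
  sarcomere length.
- **Tubular fibres** (`make_tubular_muscle`): actin on a cylindrical
  shell (default outer radius 4 µm, thickness 1.2 µm) with the tube
  axis along `y`, mitochondria as spheres assigned greedily to the core
  or the shell so the central voxel fraction lands within ~2 % of the
  requested value (default 0.7). Central spheres draw radii from the
  full 0.35–0.7 µm range while peripheral spheres are clamped to fit
  inside the shell — mirroring the small mitochondria parts wedged
  between myofibrils versus the larger central organelles, and keeping
  object size comfortably above the PSF so thresholding bias stays
  small.
- **Imaging model** (`apply_imaging_model`): separable Gaussian blur
  (per-axis σ in µm), multiplicative depth decay `(1 −
  depth_decay)^((z−1)·dz)` — a smooth monotone stand-in for
  depth-dependent signal loss — additive background, and
  sqrt-intensity (shot-like) noise, clipped at zero. Deterministic
  under its seed; all pipeline randomness derives from one config seed
  through named substreams.

What the generator does **not** emulate: real point-spread functions
(no side lobes, no depth-varying anisotropy), EM texture,
membrane-versus-matrix label differences (both labels reduce to "the
mitochondria channel"), curved myofibrils, organelle networks with
genuine connectivity, and spatially correlated noise. Passing the
recovery tests therefore demonstrates that the *computational chain* is
correct and unbiased under controlled degradations — it does not
certify segmentation accuracy on real micrographs, where deviations
from these assumptions dominate.

## Numerical choices

- Otsu thresholds use 256 levels over each slice's own range, making
  per-slice masks invariant to rescaling any single slice.
- Regional-maxima detection after h-maxima suppression uses a plateau
  tolerance of `1e-7 × max(distance)`; greyscale reconstruction
  propagates exact values (max/min operations only), so plateaus are
  exact and the tolerance only guards the marker subtraction.
- Watershed flooding breaks priority ties by insertion order, which is
  fixed by the deterministic seed labelling — identical inputs give
  identical labels.
- The EDT, reconstruction, labelling, flooding and separable
  convolution kernels are compiled (Rcpp); everything else is plain R
  on top of EBImage primitives.
- TIFF I/O never trusts resolution tags: voxel sizes travel in a YAML
  sidecar and their absence is an error, not an assumption of isotropy.
  Integer-valued stacks round-trip bit-exactly (16-bit); float stacks
  are stored at 2^-32 relative quantisation with a power-of-two scale.

## Problem sizes

The test suite and the demonstration configurations use stacks of
roughly 0.5–6 million voxels (e.g. 40 × 128 × 128 at 0.2 × 0.1 × 0.1 µm,
or 100 × 240 × 240 for the 50-object classification population) and
10–30 simulated fields or seeds per statistical check. These sizes were
chosen so that every property that should hold asymptotically (volume
convergence, unbiased fraction recovery, monotone degradation) is
already unambiguous, while a full run of everything stays in the
single-digit-minute range on one CPU core.

## Known limitations

- The watershed over-splitting bias is intentional but irreversible
  downstream; merged-object recovery is not attempted.
- Per-slice Otsu assumes each plane contains both classes; planes that
  are entirely foreground would be mis-thresholded (planes entirely
  background are handled explicitly).
- Shape classification near the 1.3/2.5 boundaries inherits the axis
  discretisation error (a few per cent at typical sizes); populations
  engineered close to a boundary will misclassify at rates the
  boundary distance dictates.
- `detect_mbands` assumes straight myofibrils aligned with `+x`; it is
  a deliberately minimal periodicity-and-peaks detector, not a general
  sarcomere tracker.
- The central/peripheral partition needs a closed actin annulus per
  cross-section; heavily fragmented shells are excluded slice-wise
  rather than repaired beyond the configured closing radius.
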