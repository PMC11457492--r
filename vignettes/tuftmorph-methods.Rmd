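---
title: "Methods: quantifying the tuft-cell cytoskeleton with tuftmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the tuft-cell cytoskeleton with tuftmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuftmorph)
```

Intestinal tuft cells carry a "tuft" of giant apical protrusions, each
supported by a core actin bundle that runs from the protrusion tip deep into
the cytoplasm as a rootlet. tuftmorph implements the quantitative image
analyses used to characterise this cytoskeletal system: filament-packing
statistics of bundle cross-sections, Fourier-space detection of lattice
order, 3D tracing of actin and microtubule networks with pitch and
dilation-overlap interaction measures, depth-resolved bundle/cell area,
apical shape descriptors, and intensity-linescan model fits. A seeded
synthetic-data generator provides every input type with known ground truth,
so each stage is testable end to end without micrographs.

## Coordinate conventions

Physical coordinates are nanometres with the origin at the image or volume
corner, x to the right, y down, and z running from the apical surface into
the cell (so depth increases with z). Pixel and voxel indices are 1-based in
R; index `(1, 1[, 1])` covers the half-open box `[0, size)` on each axis and
the centre of a pixel sits at `(index - 0.5) * pixel_size`. Pitch follows
the convention used for apicobasal structures: 90 degrees is vertical
(parallel to z), 0 is horizontal.

## The synthetic-data generator

The generator's defaults are the study conditions, not free dials:

* **Cross-sections** (`gen_lattice_points()`, `render_cross_section()`):
  a triangular lattice with centre-to-centre spacing d = 9.2 nm, clipped to
  a disc of radius (106.1 − 9.2)/2 ≈ 48.5 nm. The subtraction matters: the
  measured bundle diameter of ~106 nm covers filament *extents*, so the disc
  containing filament *centres* is one spacing smaller, and enumeration of
  lattice sites in that disc gives ~97 filaments, matching the ~100
  filaments per bundle seen in cross-sections. Disorder enters as isotropic
  Gaussian jitter of the site positions and independent site vacancies
  (isolated dislocations); complete spatial randomness (CSR, a binomial
  point process on the same disc) is the negative control for every order
  statistic. Filaments are rendered as Gaussian blobs (default PSF sigma
  2.5 nm), dark on a light background as in TEM, with additive Gaussian
  noise. The real images' noise statistics are not known to us, so the noise
  SD (default 0.02 of the unit intensity range) is an explicit, flagged
  parameter; it emulates detector noise only, not TEM structure/shot noise
  or staining texture. Passing tests on these renders therefore shows that
  the *measurement chain* is correct, not that it is robust to every TEM
  artifact.
* **3D networks** (`gen_network_volume()`): straight polymers (the pitch and
  interaction statistics only need direction and length, so curvature is
  deliberately omitted) with pitch drawn from a Gaussian centred at 81.1
  degrees (SD 5) truncated to (0, 90], uniform azimuth, and lengths uniform
  on 5–12 um; default voxels are 100 nm isotropic. A configurable fraction
  of microtubules is generated co-aligned: each copies a distinct actin
  partner's direction and span at a 200 nm lateral offset (within the reach
  of the default x4 dilation). Polymers that would leave the volume or touch
  an existing polymer of the same channel are resampled up to 100 times,
  then the generator errors — silent truncation would bias the length
  ground truth, and same-channel contact would fuse connected components
  and make per-polymer tracing ill-posed. Because paired microtubules share
  their partner's full span, simulated interaction segments are
  polymer-length-scale; the short (~1 um median) contacts seen in tissue
  reflect partial overlaps that the generator does not emulate.
* **Linescans** (`gen_profile()`): lognormal, four-parameter logistic
  (4PL), quartic, exponential-decay or constant intensity models evaluated
  on an equally spaced arclength grid with additive Gaussian noise. The
  lognormal is parameterised as `A * exp(-(ln(x/m))^2 / (2 s^2))` so its
  mode is the parameter `m` directly; the 4PL as
  `top + (bottom - top) / (1 + (x/mid)^hill)` so `bottom` is the plateau at
  the tip (x = 0).

All four generators are deterministic in (spec, seed), which the test suite
asserts bit-for-bit.

## Filament packing statistics

`detect_centers()` finds filament (or bundle) centres by scale-normalised
Laplacian-of-Gaussian filtering at sigma = spacing/(2 sqrt 2), polarity
aware, with greedy non-maximum suppression at half the expected spacing.
Subpixel positions come from separable three-point parabolic interpolation
of the LoG response at each maximum. We measured the alternative — an
intensity centroid over a half-spacing window — on rendered jittered
lattices and found it biased by neighbouring blobs (median error 0.79 nm,
max 2.9 nm, against 0.34/1.0 nm for the parabola), which materially inflates
nearest-neighbour statistics at 9 nm spacings; the local parabola is
unbiased for symmetric blobs and needs no window-size choice.

`build_neighbor_graph()` applies the 12-nm neighbour rule (roughly twice a
filament's width) as a centre-to-centre Euclidean bound; the radius is an
argument, so an edge-to-edge reading can be emulated by adding a filament
diameter. `triplet_angles()` operationalises "the angle between a filament
and two adjacent nearest neighbours" as follows: at each focal point with
degree >= 2, neighbours are sorted by azimuth and the angle at the focal
point is emitted for each azimuth-consecutive pair, including the
wrap-around pair only when degree >= 3 (a degree-2 point contributes one
angle, no wrap). This reproduces six 60-degree angles per interior point on
an ideal hexagonal lattice without double-counting arbitrary pairs.

`summarize_packing()` reports the point count, degree histogram, median
neighbour distance, median triplet angle, estimated spacing and bundle
diameter. The spacing estimate is the median over all neighbour-graph edge
lengths: under positional jitter the per-point nearest-neighbour *minimum*
is biased low (the minimum of ~6 jittered distances; ~6–9% at 5% jitter,
measured on ground-truth points), while the edge median stays within 2% of
the true spacing; for point sets with no edges it falls back to the median
unbounded nearest-neighbour distance so sparse or CSR inputs still get an
estimate. The bundle diameter is the exact minimum enclosing circle of the
centres (Welzl's algorithm) plus one estimated spacing, converting a
centre-extent into a filament-extent measure; the offset convention is
recorded in the pipeline's JSON output.

## Fourier analysis of lattice order

`power_spectrum()` subtracts the mean and applies a separable Hann window
before the FFT — the original workflow (DigitalMicrograph) does not mention
windowing, but unwindowed small regions of interest produce axis streaks
that corrupt peak detection. `detect_reflections()` searches the annulus
mapped from a real-space spacing interval (default 7–12 nm) for local
maxima and accepts "predominant" reflections by two explicit criteria:
magnitude above 50x the annulus median power, and above 5% of the strongest
peak. The background factor deserves a note: point-process speckle is
exponential-tailed, so even a featureless CSR image's annulus maximum
reaches 10–25x the median (measured over 10 seeds), while true first-order
lattice reflections measure ~10^4x; a factor of 5 would accept speckle,
50 rejects it with orders of magnitude of headroom. Accepted peaks are
non-maximum suppressed within a 15-degree angular window and completed to
centrosymmetric pairs; the ring radius is their magnitude-weighted mean
radius, and for a triangular lattice it sits at `2/(sqrt(3) d)`.

`lattice_filter()` masks the spectrum either with an annulus at the ring
radius (equidistant packing; half-width 10% of the ring radius) or with six
discs at the reflection positions (hexagonal packing; disc radius 15% of
the ring radius — "as tight as possible" made quantitative). The mask is
applied point-symmetrically so the inverse transform is real, and the
filtered image is thresholded at the 0.70 quantile of its positive values
(the manual FIJI thresholding step made reproducible) to give the
highlighted mask. `highlighted_fraction()` scores the fraction of filament
centres whose pixel is on (a search radius is available); because only
existing points are evaluated, vacancy sites never enter the denominator.
On rendered ideal lattices the hexagonal filter highlights every filament;
the measured 67–96% on real TEM is treated as a qualitative floor only,
since the micrographs are not available. To probe order *loss*, the mask
built from the ideal (jitter-free) lattice is applied to progressively
jittered renders, and the highlighted fraction falls monotonically.

## 3D networks: tracing, pitch, interaction

`trace_polymers()` labels 26-connected components and reduces each to its
longest geodesic path through the voxel adjacency graph (two breadth-first
sweeps with calibrated edge weights), which is an exact centreline for the
straight, thin polymers in scope; a voxel-thinning skeletonizer would be
needed for thick or branched masks, which we note as a limitation.
Components shorter than 0.5 um are discarded as segmentation debris. Pitch
is computed from the principal axis of the calibrated path points
(covariance eigenvector), which is robust to voxel jitter; the end-to-end
direction is reported alongside.

`interaction_map()` quantifies actin–microtubule association by dilation
overlap: the microtubule mask is dilated by the unit-radius digital
Euclidean ball (the 6-neighbour cross) applied `dilation_radius_vox` times
(default 4, reading the published "x4" as four iterated unit dilations, the
FIJI convention), and actin skeleton voxels inside the dilated reach are
marked interacting. Because the ball is symmetric this equals dilating the
actin and intersecting with microtubules, but measuring along the actin
skeleton makes the interaction length denominator the total actin length,
matching the percent-interacting definition. Whether the published overlap
lengths were measured on skeletons or raw voxels is unstated; we chose
skeletons (lengths are otherwise ill-defined for 3D blobs) and expose the
dilation radius. Interacting runs separated by at most 2 skeleton voxels
are merged to bridge single-voxel dropouts; single-voxel contacts count one
mean voxel pitch. The percent interacting is exactly
`100 * interacting length / total length`, and total length equals the sum
of trace lengths by construction.

`area_vs_depth()` measures, at depths 0/1.5/3/4.5 um below the apical
surface (depth 0 = first slice containing any cell voxel), the cell area as
on-voxel count times pixel area and the bundle area as the area of the 2D
convex hull of bundle voxels in the slice — the area *occupied* by the
bundle array, not the summed cross-sections; hull corners are taken on
pixel boundaries so a single column contributes its own pixel area rather
than a degenerate zero. Slopes come from ordinary least squares of area on
depth. `apical_shape()` returns area, perimeter and circularity
`4 pi A / P^2`; the perimeter is a marching-squares contour
(`grDevices::contourLines` at level 0.5) smoothed by a circular moving
average of the polygon vertices (window 3). Raw marching squares
underestimates circularity for discs (0.90 for a rasterized radius-50
disc); the smoothed contour gives 0.98 for the disc, 0.80 for a square
(closed form pi/4 = 0.785) and 0.03 for a 1 x 100 bar, which we consider
the right bias trade-off at these resolutions.

## Linescan fitting

`extract_profile()` samples an image along a polyline at unit-pixel
arclength steps by bilinear interpolation, averaging `width_px` (default
10, the usual linescan thickness) samples perpendicular to the local
direction; profiles run tip to base with the tip at arclength 0.
`fit_profile()` fits by Levenberg–Marquardt (minpack.lm) from a documented
initialisation — lognormal: mode at the argmax, shape 0.5, amplitude at the
maximum; 4PL: plateaus from the first/last deciles, midpoint at the
half-range crossing, hill 1; exponential decay: log-linear seed — plus four
multiplicatively jittered restarts under a fixed internal RNG, keeping the
lowest-RSS fit and never returning a fit worse than the initialisation
itself. Non-convergence yields `converged = FALSE` with best-effort
parameters rather than an error. The quartic is solved in closed form by
linear least squares. Two numerical details: lognormal arclengths at zero
are nudged by half a sample so the log is defined — nudging *only* the zero
sample (rather than shifting the whole axis) keeps the fitted mode
unbiased, which the noiseless-recovery tests require at 1e-3 relative; and
the 4PL logistic has an exact (bottom, top, hill) to (top, bottom, −hill)
symmetry, so fits are canonicalised to a positive hill slope, making
"bottom" always the tip-side plateau. The unnamed tip-to-base phalloidin
decay fit is provided as `exp_decay` (amplitude, decay length, offset) — a
documented choice selectable by flag, not a claim about the original
model. `aggregate_profiles()` resamples profiles to a common 100-point
fractional grid and fits once through the pooled cloud, mirroring a single
fit drawn through all raw traces, rather than averaging per-profile
parameters.

## Pipeline, seeds and problem sizes

`run_pipeline()` runs simulate/packing/fft/network/linescan stages from one
YAML or JSON config, validating every stage block against its schema
(unknown keys are rejected by name) before any computation. Each stage
derives its seed from the single global seed
(`global * 101 + 10007 * stage index`, mod 2^31 − 1), so any stage is
independently reproducible and a fixed-seed run reproduces byte-identical
CSV/JSON outputs (timestamps appear only in the log, never in the report,
and the report's config hash is computed over key-sorted canonical JSON so
it is stable under reordering). The `exec/tuftmorph` script exposes the
same stages as shell subcommands.

The test and acceptance workloads use 256 px cross-sections (~100
filaments), volumes of up to 340^3-scale voxel grids with 50–200 polymers,
and 30–50 profiles of 100 samples; these sizes were chosen so that every
property (oracle equivalence, parameter recovery, monotonicity, determinism)
is measured on the same regime the conditions describe while a full suite
run completes in a couple of minutes on one core.

## Known limitations

* The renderer emulates blob geometry and additive noise, not TEM contrast
  transfer, staining heterogeneity or section compression; highlighted
  fractions on renders are upper bounds relative to tissue.
* Straight-segment polymers cannot probe curvature-dependent biases in
  pitch or interaction estimates.
* Paired microtubules share their partner's full span, so simulated
  interaction-length distributions are not comparable to the short partial
  contacts measured in tissue (the percent-interacting recovery is).
* The longest-geodesic centreline assumes thin components; thick or
  branched masks need true 3D thinning before tracing.
* Segmentation itself (classifier training, local thresholding of
  probability maps) is out of scope: all 3D analyses consume binary masks.
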