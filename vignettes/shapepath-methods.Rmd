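---
title: "Cell-body shape and directional stability: models and conventions"
author: "shapepath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-body shape and directional stability: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific model behind `shapepath`, the
conventions every statistic depends on, and the design decisions that
were genuinely open. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The analysis in one paragraph

Neurons migrating out of a plated neurosphere are followed in time-lapse
(15-minute frames, 42–54 h after plating). Each cell's body is segmented
per frame from phase contrast and summarised by its moment-equivalent
ellipse; each cell's nuclear positions are linked into a trajectory,
smoothed over five time points, and differenced into movement vectors.
The first half of the recording (42–47.75 h) defines a robust *projected
path* per cell; the latter half (48–54 h) is scored against it with
three angles per frame — axis rotation, turning, and movement-vs-axis
accordance. Healthy neurons keep all three tightly distributed around
zero (a high bivariate density peak, a high ±15° accordance rate);
reelin-deficient neurons do not.

## Coordinate and angle conventions

* Pixels are 0-based with pixel-centre continuous coordinates; x grows
  rightward, y grows **down** (image convention).
* All angles are reported in standard mathematical convention
  (counter-clockwise from +x) — the image y-axis is flipped exactly
  once, inside the heading/orientation computations, never elsewhere.
* Directional angles (headings, turning) live in (-180°, 180°], with a
  reversal mapping to +180°. Axial angles (ellipse orientation, axis
  rotation, accordance) are 180°-periodic and folded to [-90°, 90°); a
  second-moment ellipse has no head, so no arrow information is ever
  attributed to it.
* Frame 0 is t = 42 h; frame k is t = 42 + 0.25 k h.

## Shape profiling

Segmentation follows the published recipe with each unstated parameter
made explicit and configurable (`segmentation_config()`):

* **Crop**: 244 × 244 px around the tracked nucleus (clamped at frame
  borders, offset recorded).
* **Edges**: sobel gradient magnitude (exact 3 × 3 shift convolution,
  replicate borders), thresholded by Otsu on the gradient by default.
  A constant crop yields an empty mask, not an error.
* **Closing**: dilation-then-erosion with a disk of radius 2 px, then
  hole filling.
* **Halo correction**: a thresholded gradient ring straddles an
  intensity step, so the filled object extends roughly one pixel beyond
  the true boundary. The boundary is therefore shifted inward by
  `halo_erode_px` (default 0.55 px) — implemented as a local disk
  average of the binary object re-thresholded at the level that moves a
  straight edge by the requested amount, because sub-pixel shifts
  cannot be expressed by binary erosion. At the ~60 px² cell sizes of
  interest a one-pixel bias would be a ~30 % area error; the recovery
  tests hold the calibrated chain to a ±5 % mean area error instead.
  The default is calibrated against this package's own renderer; real
  microscopes with different point-spread functions may need the knob.
* **Object selection**: the connected component containing the nucleus
  wins regardless of size; otherwise the nearest component within 10 px
  of the nucleus; components under 10 px are ignored; no qualifying
  component flags the frame `no-object`.
* **Ellipse**: centroid, axes and orientation from the eigenstructure
  of the plain 2 × 2 normalized second central moment matrix of the
  pixel centres (full axis lengths `4 * sqrt(eigenvalue)`; no
  discrete-pixel variance correction — the convention the brute-force
  oracle in the tests reproduces to 1e-6). Eccentricity is the
  inter-focal distance over the major axis. Collinear masks are flagged
  `degenerate`.
* **Solidity QC**: object pixels over convex-hull pixels (hull of pixel
  centres, counted on the pixel grid); fits strictly below 0.7 are
  excluded (`low-solidity`); exactly 0.7 is retained — "below the
  threshold" read strictly.
* A manual exclusion list (cell, frame) is honoured with reason
  `manual`, standing in for a by-eye review pass; all other exclusions
  are deterministic.

## Tracking

Nuclei are detected in the GFP channel by Otsu thresholding and
background-corrected intensity-weighted centroids (blobs under 4 px
ignored). Linking is gated mutual-nearest-neighbour between consecutive
frames (gate 15 px), chosen over heavier linkers because the cells of
interest are sparse and slow; there is deliberately **no gap closing**
— a missed detection splits the track, and fragments shorter than
`min_track_frames` are dropped. Positional smoothing is a centred
five-point moving average whose end windows shrink symmetrically, so
track length is preserved (this touches only the first/last two
movement vectors); movement vectors are forward differences, "adjacent
frames" read literally. Stationary frames (zero vector) carry no
heading and are excluded from angular statistics rather than assigned
one.

## The projected path

The path is fitted to first-half smoothed positions by IRLS with Tukey
bisquare weights: tuning constant 4.685, scale 1.4826 × MAD of the
residuals, at most 50 iterations, coefficient tolerance 1e-8. Two
choices matter:

* the coordinate with the larger variance is the regressor, so
  near-vertical paths cannot degenerate;
* initialisation is Theil–Sen (median of pairwise slopes) rather than
  ordinary least squares: with the larger-variance coordinate as
  regressor, a gross positional outlier becomes a *leverage* point, and
  bisquare reweighting started from OLS can lock onto it. The tests pin
  outlier resistance to within 1° of the clean-data fit.

The unit direction is signed along the cell's net first-half
displacement, so "forward" means "the way the cell was going".

## Bivariate density and its peak

The (axis rotation, turning) records are smoothed with a product
Gaussian kernel, bandwidth = kernel SD = 20° per dimension, evaluated
on 1° grids over [-90°, 90°] × [-180°, 180°]. The smoother is planar —
**no periodic wrapping** — and edge truncation is compensated by
renormalising the trapezoidal grid integral to 1 (the tests hold the
unnormalised integral to 1 ± 0.01 and the normalised one to 1e-9). The
peak is read off the grid; with a 20° bandwidth, sub-degree structure
is immaterial. Closed forms anchor the tests: a point mass yields
`1/(2*pi*20^2) ≈ 3.98e-4` per degree², independent zero-mean Gaussians
with SD σ yield `1/(2*pi*(σ² + 20²))`.

## Resampling tests and their validity envelope

Both group tests resample with replacement from a *seed* group,
recompute the statistic (KDE peak, or ±15° accordance proportion) per
trial, and count trials at or beyond the comparison group's observed
value; `p = (count + 1)/(trials + 1)`, so zero extreme trials reports a
bounded p-value, and the raw count is kept alongside. The resample size
defaults to the comparison group's record count, so the null
distribution mimics the comparison group's sampling noise; no other
scaling is applied.

This scheme models **only** the comparison group's sampling noise. Two
consequences, verified analytically and enforced by the type-I tests:

* With equal group sizes and resampling at the comparison size, the
  seed's own sampling noise is unmodelled and the one-sided test
  rejects a true null at roughly `pnorm(-qnorm(0.95)/sqrt(2)) ≈ 12 %`,
  not 5 %. The test is properly calibrated when the seed sample is
  large relative to the resample size — the regime the type-I suite
  exercises (seed 4000–8000, comparison and resample 200, fixed
  direction, 500 repetitions at 200 trials; both tests must land within
  5 % ± 2 %).
* Choosing the tail from the observed ordering (`direction = "auto"`,
  the default, mirroring how such tests are used in practice) doubles
  the nominal level under a true null; fix `direction` a priori when a
  calibrated test is needed. The chosen direction is always recorded in
  the result.

The bootstrap's duplicate records also inflate KDE peaks slightly when
the resample size approaches the seed size — a second reason the
calibrated regime keeps the seed sample an order of magnitude larger.

Shape metrics are compared per metric with an unpaired two-tailed t
test; an F test of variance equality at α = 0.05 selects Student's or
Welch's variant. No multiple-testing correction is applied across the
four metrics, matching the protocol being reproduced; note it, don't
add it.

## The synthetic-data generator

The generator is the package's test bed and defines its study
conditions; its defaults are the published group constants and are not
tuned per run.

* **Shape**: (area, eccentricity) are the sampled pair — HC
  60.6 ± 16.8 px² and 0.719 ± 0.143, RELN-del 44.1 ± 15.6 px² and
  0.767 ± 0.145 — converted to axes via `area = pi*major*minor/4` and
  `minor/major = sqrt(1 - ecc²)`. The four published axis/area means
  are not mutually consistent under independent axis draws, and area
  and eccentricity are what the pipeline measures most directly, so
  axis-length recovery is deliberately not a calibration target.
  Samples are truncated (area > 10 px², ecc clipped to [0, 0.99]);
  shape is constant within a cell (per-frame jitter is an optional
  knob, default 0, since nothing in the protocol describes shape
  dynamics).
* **Motion**: each cell starts on a ring around a virtual aggregate
  (radius auto-sized so all cells fit at the 25 px minimum spacing;
  violating placements are redrawn) and heads outward. Per step the
  heading is the outward base heading plus independent wrapped-normal
  turning noise — mean-reverting rather than a random walk, so the
  turning-angle distribution about the projected path is stationary.
  Step lengths are positive with mean `speed_px_per_frame` (default
  2 px/frame; no physical pixel size is specified by the protocol, so
  physical units are left to configuration).
* **Axis coupling**: the major-axis orientation is the *locally
  averaged* movement direction (five-frame window, matching the
  pipeline's positional smoothing) plus wrapped-normal coupling noise,
  folded to the axial range. Coupling to the five-frame average rather
  than the instantaneous heading reflects that a cell body reshapes on
  the ~1 h timescale of sustained movement, not frame-to-frame jitter —
  and it makes `sigma_couple_deg` exactly the dispersion of the
  accordance angle the pipeline measures. Under instantaneous coupling
  the measured accordance dispersion would be
  `sqrt(0.8*sigma_turn² + sigma_couple²)`, and the generator could not
  be calibrated to a target accordance rate independently of the
  turning noise.
* **Calibration**: `calibrate_coupling(p, w)` inverts the folded
  wrapped-normal central mass — e.g. a 39.6 % ±15° rate gives
  σ ≈ 28.9°, and 32.8 % gives σ ≈ 35.4°. `calibrate_peak_density`
  seeds σ from the Gaussian convolution closed form
  `1/(2π(σ² + h²))` and refines it by simulation through the
  pipeline's own KDE (100,000 pairs, two iterations), absorbing the
  axial folding and grid renormalisation the closed form ignores
  (~2 % at the HC level).
* **Rendering**: phase frames are mid-gray (110) with a brighter
  interior (172) and a dark rim (52) centred ~0.9 px inside the
  boundary, with band-limited edges (logistic transition, 0.7 px scale)
  emulating diffraction-limited optics; nuclear frames carry a Gaussian
  blob (SD 2.2 px) per centroid; both channels get Gaussian noise
  (default SD 3) and 8-bit quantisation ("256 gradations"). The
  ground-truth mask of any rendered ellipse is recoverable
  (`true_ellipse_mask`) for oracle tests. Cells whose ellipse leaves
  the field are truncated from the rendered ground truth.
* The five-point smoothing attenuates frame-level turning noise by
  roughly `sqrt(5)`, so track-level turning dispersions measured by the
  pipeline sit below the frame-level `sigma_turn_deg`; peak-density
  recovery is therefore specified on directly drawn (rotation, turning)
  pairs, while accordance recovery runs through the full track
  pipeline, where the coupling construction makes it exact up to
  binomial noise.

What the generator does **not** emulate: neurite/process morphology,
cell–cell contact, division, uneven illumination, focus drift, or
densely packed fields. Passing tests certify the pipeline's internal
correctness and its statistical calibration — not robustness to those
real-data complications.

## Problem sizes and numerical tolerances

The test suite runs the moment-fit oracle at 1e-6 relative tolerance;
angle range contracts on 10⁶ random inputs; KDE grid integrals at
1 ± 0.01 (pre-normalisation) and 1 ± 1e-9 (post); accordance-rate
recovery at 785 and 1032 records (three binomial standard errors);
KDE-peak recovery at 785 pairs (15 % relative, the sampling noise at
that size); segmentation recovery on 60 rendered cell-frames (mean area
error ≤ 5 %, mean orientation error ≤ 5° above eccentricity 0.3 — at
~60 px² the pixel-quantisation floor alone approaches that bound near
eccentricity 0.3); and both type-I calibrations at 500 repetitions of
200 trials. Resampling tests default to the published 10,000 / 1,000
trial counts; the suite uses reduced counts (200–1000) where the
distributional question does not require more.

## Known limitations

* Segmentation assumes one sparse cell per crop neighbourhood; dense
  fields and touching cells are out of scope.
* The halo correction is calibrated for this renderer's edge profile;
  on real optics it is a free parameter.
* Orientation is intrinsically ill-determined for near-circular bodies;
  downstream statistics inherit that noise below eccentricity ~0.3.
* The linking stage has no gap closing by design; heavy detection
  dropout shortens tracks rather than bridging them.
* The resampling tests are one-sided and, outside the large-seed
  regime, anti-conservative (see above); interpret p-values from
  equal-sized groups accordingly.
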