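---
title: "Measuring radial chromosome territory positions: methods and design"
author: "radialFISH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring radial chromosome territory positions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialFISH)
```

# The measurement problem

A chromosome territory's radial position — where it sits along the
periphery-to-center axis of the interphase nucleus — is a robust,
biologically regulated property: it differs between chromosomes, changes
when fibroblasts exit the cell cycle, and is perturbed in laminopathies.
Two complementary measurements are standard. For flattened 2D FISH
preparations, the *erosion-shell analysis* divides the DAPI-defined nucleus
into five concentric shells of equal area and asks what fraction of the
chromosome-paint signal falls into each, normalized to the DNA (DAPI)
fraction. For 3D-preserved nuclei imaged as confocal z-stacks, the distance
from each territory's geometric center to the nearest point of the nuclear
periphery is measured in three dimensions.

This vignette explains how the package implements both, the assumptions
involved, and the design decisions taken where the classical protocol is
silent.

# The 2D erosion-shell analysis

## Segmentation

The nucleus support is obtained from the DAPI channel by a global Otsu
threshold computed on the channel's own intensity range (which makes the
partition invariant to affine intensity rescaling), followed by hole
filling and retention of the largest connected component. Interactive
outlining — the historical practice — can be emulated by passing a
user-supplied mask to `segmentNucleus()`. Nuclei touching the image border
are rejected outright: both shells and periphery distances are undefined
for clipped nuclei. If a secondary component reaches 25% of the largest
one, the segmentation is flagged with a warning (the largest is kept);
below that, satellites are treated as debris.

Ellipse axes are estimated from the second central moments of the binary
mask: a uniform ellipse with semi-axis $a$ has coordinate variance $a^2/4$
along that axis, so the full axis lengths are $4\sqrt{\lambda_i}$ for the
two eigenvalues of the mask covariance (converted to µm). For z-stacks the
fit uses the largest-area slice, which corresponds to the conventional 2D
reading of "major axis" and "minor axis".

## Equal-area shells by distance-transform quantiles

The shells are defined by the Euclidean distance transform of the mask
(distance of each pixel to the nearest background pixel). Mask pixels are
sorted by `(distance, row-major index)` ascending and cut into five
consecutive groups whose sizes differ by at most one pixel; the group with
the smallest distances is shell 1, the periphery. Spare pixels from integer
division go to the outermost shells, and the index tie-break makes the
partition fully deterministic — two properties asserted by the test suite
on a thousand randomly perturbed masks.

The quantile construction, rather than literal iterated morphological
erosion, is deliberate: each one-pixel erosion peels a full ring whose area
depends on the current perimeter, so iterated erosion cannot produce shells
of exactly equal area. The distance-transform formulation is the limit of
infinitesimal erosion steps and achieves equality up to integer rounding.

## Per-shell measurement and normalization

For each shell the DAPI and probe intensities are summed and expressed as a
percentage of that channel's in-mask total; the normalized proportion is
`probe% / DAPI%` per shell. The ratio is 1 in every shell exactly when the
paint is distributed like bulk DNA, which the suite asserts to 1e-6 for a
probe channel proportional to DAPI.

Two error cases are explicit rather than silent: a probe channel with zero
in-mask signal (failed hybridization) and a DAPI percentage of zero in any
shell (degenerate staining) both abort the profile.

**Background handling.** The normalized ratio is invariant to per-channel
*scaling* but not to additive *offsets*: a camera pedestal pushes every
shell toward 1 and flattens real position differences, because the pedestal
integrates over each shell's thousands of pixels while the paint signal
occupies comparatively few. `measureShells(backgroundSubtract = TRUE)`
therefore estimates each channel's background from the out-of-mask pixels
and subtracts `background × shell area` from the shell sums. Three
estimator choices matter and are worth recording:

* the background *level* is the out-of-mask **median** by default. For a
  symmetric background distribution the median and the mode estimate the
  same location, but the median's sampling error is an order of magnitude
  smaller — and that error is multiplied by ~10³ pixels per shell. A
  kernel-density mode (`estimator = "mode"`) is available for skewed
  backgrounds.
* subtraction happens on the **shell-aggregated sums**, not pixel-by-pixel:
  per-pixel subtraction with clipping at zero converts symmetric noise in
  signal-free shells into a half-normal residual whose sum biases dim
  shells upward.
* subtracted shell sums that are statistically indistinguishable from zero
  (below `denoiseSigma = 2` times the shell-summed background noise SD) are
  set to exactly zero — a symmetric hard threshold. Without it, truncating
  negative noise sums at zero leaves, again, a positive residual (~1% of
  signal share per empty shell) that drags every cohort's profile center of
  mass toward the uniform value 3. On synthetic ground truth this
  calibration brings cohort centers of mass close to their closed-form
  values (the acceptance script reports them per condition).

Subtraction is **off by default**, matching the classical protocol, which
does not mention it; cohort-level studies in this package's own tests and
acceptance script run with it enabled because the synthetic camera model
includes an explicit pedestal (below).

## Cohort statistics

`aggregateProfiles()` reports per-shell mean and SEM (sample SD / √n) over
nuclei; a cohort below 50 nuclei warns, since the analysis is
conventionally run on populations of more than 50 images.
`compareShells()` performs an unpaired two-tailed Welch test per shell —
unequal variances, Welch–Satterthwaite degrees of freedom — implemented
directly from the formula and cross-checked against `stats::t.test()` in
the unit tests. No correction is applied across the five shells by default,
matching the conventional per-shell P < 0.05 marking of shell histograms; a
Bonferroni option exists. Degenerate zero-variance comparisons follow fixed
conventions (equal means → P = 1; unequal means → P = 0, flagged).

`classifyPosition()` condenses a mean profile into the verbal categories
used in the field via its center of mass over shells,
$c = \sum_k k\,m_k / \sum_k m_k$: peripheral if $c \le 2.4$, interior if
$c \ge 3.6$, intermediate otherwise. The thresholds are a convention of
this package (symmetric about the uniform-profile value 3), exposed as
parameters, and should not be mistaken for a community standard. They are
deliberately tight on the peripheral side: a cohort of 50 nuclei with two
territories each has an irreducible sampling SD of roughly 0.08 on $c$, so
cohorts drawn from a moderately peripheral law sit within ~2 SD of the 2.4
boundary — the label is meaningful only together with the shell histogram
and the per-shell tests.

# The 3D distance analysis

Stacks are segmented with a single Otsu threshold computed over all voxels
(per-slice thresholds are ill-posed for slices above and below the nucleus
that contain only noise), holes filled per slice, largest 3D component
kept. Territories are segmented inside the mask by Otsu on the in-mask
probe intensities after a light per-slice Gaussian blur (σ = 1 px,
disableable): paint channels carry additive noise whose clipped
distribution otherwise drags the threshold into the noise floor and
fragments it into spurious ~20-voxel components. Components below
`minVolume` (default 20 voxels) are discarded; a count different from the
expected two signals per autosome warns but does not abort.

The *geometric center* is the unweighted centroid of the territory voxel
set — not intensity-weighted, which would be a different estimator. The
periphery distance `d_raw` is the minimum anisotropic Euclidean distance
(µm) from that center to any boundary voxel of the mask (mask voxels with a
face-adjacent background neighbor). Because only one point per territory is
queried, the implementation minimizes over boundary voxels exactly
(vectorized); the test suite checks it against an independent plain-loop
oracle with its own boundary detection, to machine precision, and checks on
noise-free ellipsoids that a center-placed territory returns the smallest
semi-axis within one voxel diagonal. Two size normalizations divide by the
fitted (major+minor)/2 or the major axis alone; frequency-distribution
curves (`frequencyCurve()`, default bins 0.5 µm for raw distances) make
conditions comparable, and the tests verify that the *ordering* of
condition medians is invariant to which of the three measures is used when
cohorts share a nucleus-size distribution.

# The synthetic scene generator

The generator exists so that every stage of the pipeline can be validated
against known ground truth. One `SceneConfig` plus its seed determines
every raster bit-for-bit; each nucleus index derives an independent
sub-seed, and generator calls never disturb the caller's RNG stream.

A nucleus is an ellipse (2D) or ellipsoid (3D) centered in the field,
optionally perturbed by a low-order Fourier modulation of its boundary
radius (harmonics 2–4, amplitude `nucleusIrregularity`) to emulate
irregular nuclear outlines; the DAPI channel is a flat plateau with a
one-pixel soft edge centered on the boundary, so that threshold
segmentation recovers the analytic area. Territories are isotropic
Gaussian blobs (σ = `territoryRadius`/2) or hard discs placed at a radial
coordinate $r \in [0,1]$ drawn from a Beta law, along a uniformly random
direction; $r$ is the *elliptical* scale coordinate (the point lies on the
boundary contour shrunk by $r$), so it means the same thing in every
direction. The named laws are Beta(8,2) ("peripheral", mean 0.8),
Beta(7,3) ("intermediate") and Beta(2,8) ("interior"); under equal-area
shells their expected signal centers of mass fall in shells 1–2, near 3,
and in shell 5 respectively (closed-form Beta probabilities over the
equal-area band edges $r = \sqrt{1-k/5}$), which is what makes them usable
as ground truth for `classifyPosition()`. Custom (α, β) laws support
sweeps, e.g. the monotone-recovery property test.

Both channels sit on a camera pedestal (`baselineLevel`, default 0.15) with
additive Gaussian noise (`noiseSd`, default 0.05, clipped at zero — at
three SD below the pedestal the clip is essentially inactive). The pedestal
is deliberate: it reproduces the offset sensitivity of the normalized
ratio, the failure mode the background-corrected estimator exists for. The
defaults emulate the study conditions the analysis is meant for: 2D fields
of 128×128 px at 0.2 µm/px with nucleus semi-axes 10 × 6.5 µm (flattened
fibroblast nuclei), and 3D stacks of 96×96 px × 40 slices at 0.2 µm
laterally and 0.2 µm axially with semi-axes 8 × 5 × 2.5 µm; two territories
of radius 1 µm per nucleus.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: point-spread-function blur and chromatic
shift, photon (Poisson) statistics, photobleaching, irregular territory
shapes (real territories are convoluted domains, not Gaussian blobs),
chromatin texture in the DAPI channel, and multi-nucleus fields. The
generator validates the *measurement machinery*, not the microscope.

# Numerical conventions and degenerate inputs

* Shell tie-break: `(distance, row-major index)`, ascending; spare pixels
  to the outermost shells.
* Masks smaller than the shell count, blank DAPI channels, empty probe
  channels, zero-variance comparisons, all-zero profiles and non-positive
  bin widths raise typed errors with stage-attributed messages rather than
  propagating NaNs.
* TIFF interchange stores both channels in one 32-bit float multi-page
  file, divided by a common per-file factor to satisfy the [0,1] baseline;
  all analyses are invariant to that common scaling.
* Sub-seeds are derived as `(seed * 20011 + index * 7919) mod (2^31 - 1)`,
  exact in double arithmetic for 32-bit seeds.

# Problem sizes

The test-suite and acceptance-script simulations use the cohort sizes the
analysis is designed around: 50 nuclei per 2D condition (three conditions
for law recovery; 20 replicate pairs for the type-I simulation) and 20
stacks per 3D condition, with equal-area and oracle checks on hundreds of
random masks and small stacks. These sizes keep the full validation suite
in the low minutes on a single core while leaving the statistical
assertions comfortably powered.

# Known limitations

* Shell analysis is inherently 2D; applying it to projected stacks is not
  implemented (nor recommended).
* The classifier's thresholds are a package convention; report the center
  of mass alongside the label.
* Background correction assumes a spatially uniform pedestal; structured
  background (vignetting, gradients) would need flat-field correction
  upstream.
* The 3D periphery is the voxelized mask surface; no sub-voxel surface
  smoothing is attempted, so distances carry a half-voxel-scale
  quantization error.
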