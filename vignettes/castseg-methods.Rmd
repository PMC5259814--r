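---
title: "Local midway thresholding and WSS analysis: models, parameters, numerics"
author: "castseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local midway thresholding and WSS analysis: models, parameters, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(castseg)
```

This vignette explains the models implemented in `castseg`, the parameters
that matter, the numerical choices behind them, and what the synthetic
phantom can and cannot tell you about real micro-CT data.

## The segmentation model

The vessel of interest is the right common carotid artery (RCCA) of a mouse
carrying a tapering shear-modifying cast (inner diameter 400 → 200 µm over
1.5 mm). Contrast-enhanced micro-CT renders the lumen bright (hundreds of
HU) against soft tissue (tens of HU), but two effects defeat a single
global threshold:

* **in-cast signal drop** — the compressed lumen holds less blood and hence
  less contrast agent, so the lumen mean falls (published cross-animal
  averages: 339 HU outside vs 257 HU inside the cast), while the local
  background becomes the cast material itself (−97 HU);
* **axial fluctuation** — both lumen and background intensities fluctuate
  along the vessel.

The protocol therefore computes a *local* threshold per cross-sectional
contour. For contour $i$, the lumen region is the contour shrunk to 80% of
its radius and the background region is the annulus between the 120%- and
140%-expanded contour. With region means $L_i$ and $B_i$, the midway
threshold is

$$T_i = \tfrac12 (L_i + B_i), \qquad T_g = \operatorname{mean}_i T_i ,$$

where $T_g$ is the conventional global threshold used as comparator. The
20% / 20–40% factors are tied to the imaging geometry: the narrowest lumen
(200 µm) spans 5 voxels at 40 µm resolution, so a 20% shrink or expansion
moves the region boundary by at least one voxel, keeping the lumen region
free of boundary voxels and the background annulus clear of the lumen.
Both factors are exposed (`shrink`, `expand`) but defaulted.

Contours are represented radially, $r(\theta)$ at $K = 72$ uniform angles
(5° resolution), about the centerline point. This matches the per-contour
nature of the protocol and makes the shrink/expand scalings exact
similarities. The representation is star-convex by construction;
non-star-convex lumens (which do not occur for this vessel) are out of
scope and would surface as refinement errors, not silent corruption.

## From manual tracing to an automated loop

The reference procedure traces vessel borders manually on longitudinal
planes at three rotations (0°, 60°, 120°) and iterates manual contour
correction against binarized images. `castseg` keeps the manual entry path
— `interpBorderContour()` builds a contour from ≥ 6 (θ, r) border samples by
periodic cubic spline — but automates the loop:

1. cross-sections are extracted *perpendicular* to the centerline (10 µm
   in-plane spacing, trilinear interpolation), where radial regions and
   diameters are well defined;
2. region statistics → local thresholds as above;
3. each contour is refined by casting $K$ rays from the centerline point
   and taking the first subpixel crossing of the interpolated intensity
   below the threshold (quarter-pixel steps, linear interpolation between
   the bracketing samples);
4. the refined boundary is smoothed by periodic Fourier truncation keeping
   8 harmonics — the algorithmic stand-in for manual cleanup of single-ray
   spikes;
5. regions are re-derived from the refined contours and steps 2–4 repeat
   until the maximum radial change falls below a tenth of a voxel (4 µm),
   typically 2–3 passes (`passes = 4` caps the loop).

Step 5 deserves a note, because a single refinement pass is the more
literal reading of the written protocol. We iterate by default for a
measured reason: with one pass, the result inherits the initial contours
through the background annulus. At the distal cast the lumen is ~5 voxels
wide and the 1.2–1.4× annulus of a perturbed initial contour straddles the
steep lumen–cast transition, so ±15% initial-radius jitter moves $B_i$ by
tens of HU and the final diameter by up to ~10% on the worst slice.
Iterating to convergence makes the fixed point essentially independent of
the initialization (worst-slice differences drop below 2%), which is what
the protocol's own reproducibility requirement (< 5% between repeated
segmentations) demands — and is arguably what the manual
modify-until-satisfied loop did implicitly. `passes = 1` restores the
single-pass behaviour.

Slices whose background annulus would leave the sampled plane (or whose
plane leaves the volume) are dropped with a `WARN` message rather than
failing the run; refinement failures (off-lumen ray origin, > 10% of rays
without a crossing) are hard errors carrying the arc position, because they
indicate a broken centerline or threshold rather than an edge effect.

## Centerline and frames

The centerline is a natural cubic spline through ≥ 4 ordered center points
(any density; the curve is resampled at uniform arc length, default 40 µm).
In-plane bases are propagated by rotation-minimizing double-reflection
transport rather than Frenet frames, which are undefined on straight
segments and flip at inflections; the transported frames also align the
angular origin between slices, which the surface lofting relies on.

## The synthetic phantom

No image data are deposited with the study, so validation runs on a
synthetic volume with known truth. The generator emulates:

* a tube of bright lumen along z with a gentle sinusoidal in-plane offset
  (amplitude 200 µm, period 8 mm) so cross-sections are genuinely oblique;
* the cast as a low-HU annulus (−97 HU) from the tapering inner diameter
  out to a 1 mm outer diameter over the cast extent;
* lumen compression inside the cast: true lumen diameter = cast inner
  diameter − 2 × 13.5 µm wall; the thin wall itself is soft tissue at
  background HU;
* a continuous entrance/exit transition (0.3 mm, about one vessel
  diameter) over which the lumen radius and contrast blend between the
  free state (radius 250 µm, 339 HU) and the in-cast state — a vessel
  necks into a cast smoothly, and the truth profile is required to be
  continuous;
* axial lumen fluctuation as a sinusoid of ±10% of the lumen–background
  contrast with 1.5 mm period — the published data report only per-region
  SDs, so the spatial correlation of the real fluctuation is unknown and a
  single smooth mode is the least-committal choice;
* partial volume by supersample-and-average (3³ subsamples per voxel, a
  box filter of one voxel width) — no detector PSF, ring artifacts or beam
  hardening;
* i.i.d. Gaussian noise (SD 30 HU, within the published per-region SD
  range) added after averaging, then rounding to signed 16-bit integers.

The default grid is 160 × 160 × 300 voxels at 40 µm (6.4 × 6.4 × 12 mm)
rather than the scanner's 512³ — the RCCA region of interest fits with a
wide margin and the tests stay fast. The non-cast radius (250 µm) is a
typical murine common carotid value; the publication never states it.

What passing tests on this phantom do **not** show: robustness to beam
hardening, rings, motion, neighbouring bright structures (jugular vein),
bifurcations, or plaque-narrowed lumens. The phantom isolates exactly the
two effects the local threshold targets (in-cast drop, axial fluctuation)
plus partial volume and noise.

## Geometry

Diameters are equivalent-area diameters $D = 2\sqrt{A/\pi}$ with $A$ the
shoelace polygon area of the sampled contour — rotation invariant and
matching the single-number "vessel diameter" usage. At $K = 72$ a polygonal
circle carries a 0.06% discretisation factor in $D$; tests account for it
explicitly. Wall thickness inside the cast is
$w(s) = (D_\text{cast}(s) - D_\text{vessel}(s))/2$; negative values are
flagged as overshoot, not raised.

Surfaces are lofted from contour stacks (triangulated quad strips between
consecutive contours, fan caps to the end centroids, outward orientation
checked via signed volume) and smoothed with Taubin λ/µ band-pass steps
(20 passes, λ = 0.5, µ = −0.53 — inside the standard stability band
µ < −λ). Smoothing is gated: if the enclosed volume changes by more than
1% the call errors instead of returning a shrunken mesh; measured changes
on smooth cylinders are ~0.4% (residual λ/µ imbalance on the 72-gon plus
end-cap pull — the idealized expectation of < 0.1% is not met by the
uniform-weight umbrella operator, and we report the measured band).
Flow extensions extrude each end contour along the end tangent for exactly
5 end radii, replacing any centerline curvature beyond the stack's range so
the extension is genuinely straight.

## Hemodynamics

The Doppler inlet trace is ensemble-averaged peak-to-peak over 5 cycles
(the figure caption of the source says 4; the count is an argument), with
the fundamental period estimated from the periodogram so noisy systolic
peaks are not double-counted, then low-pass filtered by Fourier truncation
(mean + 8 harmonics, preserving the mean exactly). Doppler velocity is
interpreted as the centerline peak of a parabolic profile
($Q = \tfrac12 U \pi r^2$; `plug` selectable) — the conversion is not
stated in the source.

The 3D Navier–Stokes solve is explicitly out of scope. WSS uses the
fully-developed Poiseuille surrogate

$$\tau(s,t) = \frac{4 \mu Q(t)}{\pi r(s)^3},$$

with blood as Newtonian fluid (µ = 3.5 × 10⁻³ kg/m/s, ρ = 1060 kg/m³).
At the murine carotid's Reynolds number (order 10 by
$Re = 4\rho Q / (\pi \mu D)$; the source prints $Re = 7$ without stating
its convention, which we do not reproduce) the viscous solution is near
fully developed except at the cast exit jet; the surrogate cannot produce
the post-cast asymmetric jet, recirculation, or any nonzero OSI — the OSI
machinery is still exact for externally computed τ(s, t) tables, which
`readWSSField()` ingests so TAWSS/OSI post-processing stays
solver-agnostic. The Womersley pulsatility correction is omitted (the
Womersley number is small at r ≈ 250 µm and murine heart rates); this is a
documented limitation, not a flag.

TAWSS is the trapezoidal time-average of |τ| over one period; OSI is
$\tfrac12 (1 - |\int \tau\,dt| / \int |\tau|\,dt)$, defined as 0 where the
magnitude integral vanishes, and clamped to $[0, \tfrac12]$ against
rounding.

## Problem sizes and tolerances

The test suite and the acceptance script run the full protocol on the
default phantom: ~286 slices at 40 µm spacing, 72 rays per contour, 10 µm
in-plane sampling — a segmentation converges in 2–3 passes in a few seconds
on one CPU, and the whole suite in under two minutes. Key tolerances:
convergence at a tenth of a voxel (4 µm); refinement steps a quarter pixel
(2.5 µm); frame validity at < 10° twist between consecutive samples;
contour positivity and uniform angular spacing enforced by class validity.
Degenerate inputs (constant images, zero-radius contours, empty regions,
all-missing summary tables, fewer cycles than requested) error with
specific messages rather than propagating NaNs.

## Known limitations

* Star-convex contours only; bifurcations and plaque-intruded lumens are
  out of scope.
* The phantom's noise is white and its fluctuation a single sinusoid; real
  scanners correlate both.
* The quasi-1D surrogate cannot reproduce downstream jet asymmetry or
  nonzero OSI; upstream-of-cast conclusions are the reliable ones.
* MetaImage I/O is not provided; volumes travel as NIfTI.
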