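---
title: "Methods: quantifying bacterial cellulose structure and mechanics"
author: "pellimetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying bacterial cellulose structure and mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pellimetrics)
```

# Scope

Bacterial cellulose grows as a macroscopic pellicle — a film of entangled
cellulose fibers produced at the air–medium interface of a *Komagataeibacter*
culture. Each fiber is a two-phase object: ordered (crystalline) domains
alternate with disordered (amorphous) domains along its length. pellimetrics
quantifies this material at both scales and connects the structure to
mechanics:

* **fiber scale** — single stained fibers are imaged as blinking-fluorophore
  TIRF timelapses, reconstructed by super-resolution radial fluctuations
  (SRRF), and segmented into bright (amorphous, dye-rich) and dark
  (crystalline) domains; the fiber crystallinity is the length fraction of
  dark domains;
* **pellicle scale** — wide-angle X-ray scattering (WAXS) frames are reduced
  to 1D diffractograms and decomposed into crystalline reflections plus an
  amorphous halo; the crystallinity index is the area fraction above the
  fitted background on 2θ ∈ [10°, 45°];
* **chemistry** — Raman spectra are smoothed, background-subtracted and
  normalized, and the acetylation carbonyl band near 1740 cm⁻¹ is tested for
  presence;
* **mechanics and density** — wet dogbone specimens give engineering
  stress–strain curves (modulus, strength); a side-view photograph plus dry
  mass gives the equivalent-cylinder density;
* **statistics** — one/two-way ANOVA with Bonferroni-corrected pairwise
  tests, and Pearson correlations between density and mechanics.

Every input has a seed-deterministic synthetic generator with stored ground
truth, so the full pipeline is testable without instrument data.

# Single-fiber crystallinity

## Imaging model of the generator

`genFiberStack()` renders a fiber as a polyline whose arclength is divided
into alternating crystalline and amorphous domains. Fluorophores are placed
as a Poisson process along the amorphous domains only (the cellulose-binding
dye stains disordered regions preferentially; a finite `contrast_ratio`
allows partial staining of crystalline domains, the default is strictly
dark). Each emitter blinks independently per frame (Bernoulli with
`blink_prob`) and is rendered as a Gaussian PSF spot; shot noise is Poisson
on the expected photon image.

Default realism parameters and why:

* domain lengths around 510–600 nm (crystalline) and 167–192 nm (amorphous),
  i.e. a crystallinity near 75% — the scale reported for bacterial cellulose
  fibers (`randomFiberTruth()`);
* `pixel_size_nm = 65` and `psf_sigma_px = 1` — a 100× high-NA TIRF setup
  (σ ≈ 0.21 λ/NA ≈ 65 nm for blue emission);
* `emitter_density_um = 250` — one binding site every ~4 nm, emulating the
  quasi-continuous labeling of a minor-groove cellulose dye at high
  concentration. Radial-fluctuation reconstruction *requires* a densely
  labelled structure with sparse per-frame activation: if whole 200-nm
  segments light up as one object every frame, each segment collapses into a
  single diffraction-limited blob and its apparent width no longer reflects
  the domain length;
* `blink_prob = 0.2` and 100 frames — sparse enough that simultaneously
  active emitters within a segment are few, while the lag-1 temporal
  statistics (about `n p²` ≈ 4 co-activations per emitter) remain well
  sampled.

These values were fixed as the generator's study conditions while the
pipeline was designed, and are not tuned per test.

## SRRF reconstruction

`radialityMap()` evaluates, for every subpixel of the magnified grid, how
strongly local intensity gradients converge onto it: gradients are sampled
at `axes` points on a ring of radius `ring_radius_px` (defaults 8 and 0.5 as
in common practice), each ring point contributes
`sign · max(0, 1 − d/r)` where `d` is the perpendicular distance from the
subpixel center to the gradient line and the sign distinguishes converging
from diverging gradients. Gradients are the analytic derivatives of the
Catmull–Rom bicubic interpolant of the frame, evaluated as precomputed
weight-matrix products, so a whole magnified frame costs a few matrix
multiplications. Gradient magnitudes below 10⁻⁶ of the frame's dominant
gradient are treated as orientation-free and contribute zero; this keeps the
map exactly zero on constant frames and stable under constant intensity
offsets (offset invariance holds to ~10⁻⁵ relative — the limit set by
floating-point cancellation, not by the algorithm). By default the map is
weighted by the interpolated intensity.

`tracReconstruct()` clips negative (divergent) radiality to zero and
combines frames by the order-2 temporal auto-correlation: the mean of
pairwise products of consecutive frames (`trac_lag = 1`). A temporally
constant stack therefore reconstructs to the squared radiality map, and a
`trac_lag = 0` variant (the mean square) is invariant to frame order.
`driftCorrect()` registers every frame to the first by FFT cross-correlation
with parabolic subpixel refinement; correction is on by default.

The magnified grid convention: subpixel `(i, j)` (1-based) has its center at
`(i − 0.5)/M + 0.5` in original pixel coordinates, so a raw coordinate `x`
maps to magnified coordinate `(x − 0.5)·M + 0.5`.

## Profile extraction and domain segmentation

`extractProfile()` resamples the trace at a fixed arclength step and
averages the image over a 3 µm-wide transverse segment at each step — wide
transverse averaging suppresses off-fiber noise without blurring along the
fiber. `analyzeFiberStack()` reads the profile from the reconstruction on
**amplitude scale** (the square root of the order-2 correlation map). For
sparse independent blinking the lag-1 correlation at a point is proportional
to the squared emitter density there, so the square root restores a signal
approximately linear in density — and half-maximum edge positions of a
symmetric band are preserved under linear imaging, which is what makes the
FWHM an estimate of the true domain length. The profile is then smoothed
with a 40 nm Gaussian (kernel FWHM ≈ 94 nm, just below the 100 nm resolution
floor) to remove sub-resolution speckle from the finite co-activation
statistics.

`findPeaksFiltered()` detects local maxima with their topographic prominence
(height above the higher of the two saddles toward larger terrain) and
applies three filters in a fixed order: (1) peaks with FWHM < 100 nm are
discarded, (2) of any pair closer than 100 nm the less prominent peak is
dropped (closest pair first, re-evaluated), (3) peaks with prominence
strictly below the per-fiber median of the survivors are discarded — ties at
the median are retained. The 100 nm floors are the resolution of TIRF
microscopy. FWHM is measured at half of (height − local base), the local
base being the higher of the two adjacent inter-peak minima; half-maximum
crossings are linearly interpolated between samples (a documented
`global_baseline` flag switches to the global profile minimum).

`segmentDomains()` takes bright lengths as the retained peak FWHMs and dark
lengths as the distances between the descending half-maximum edge of one
peak and the ascending edge of the next; the stretches outside the outermost
peaks are discarded (neither dark nor bright). The crystallinity is
100 · Σdark / (Σdark + Σbright).

## What passing tests show — and what they do not

End-to-end recovery on the default conditions is 73 ± 2.5% for a true 75%
(slight negative bias: amplitude-scale edges of short segments are still
marginally widened by the PSF). Two structural caveats, visible in the
tests, carry over to real data:

* because dark counts are one fewer than bright counts, short fibers with
  few domains bias the ratio; reliable estimates need many domains per fiber
  (the property tests use 16 domain pairs, matching the hundreds of peaks
  per strain a real experiment pools);
* the median-prominence cut assumes genuine peaks are more prominent than
  spurious ones. When all peaks have near-identical prominence it discards
  half of the *genuine* peaks, and skipped amorphous domains are then
  counted as dark stretches — at low true crystallinity this inflates the
  estimate. The estimator is trustworthy in the regime of real cellulose
  fibers (crystallinity well above 50%), which is where the monotonicity
  property is asserted.

The generator does not emulate fiber curvature, crossing fibers (traces are
inputs and assumed isolated), dye photobleaching, or correlated on-times.

# WAXS crystallinity, lattice spacing, crystallite size

`genDiffractogram()` builds patterns as pseudo-Voigt reflections at the
cellulose Iβ positions (14.9°, 16.7°, 20.5°, 22.9°, 34.5° 2θ for Cu Kα;
shipped as a packaged reference table used for initial peak centers) on a
broad Gaussian amorphous halo; peak areas are scaled so the area-based
crystalline fraction over [10°, 45°] equals the requested value by fine
quadrature of the noiseless components. `genDetectorImage()` renders an
isotropic flat-detector frame (default geometry: 50 mm distance, 75 µm
pixels, λ = 1.54 Å, beam center at the frame center) whose azimuthal
integration reproduces the pattern; an optional masked slit band emulates
detector module gaps, and `mergeLineEraser()` combines two shifted exposures
by the per-pixel mean of unmasked contributions.

`integrateAzimuthal()` assigns each pixel 2θ = atan(r/D) and averages into
equal-width 2θ bins; masked pixels are excluded and empty bins flagged NA.

`fitBackground()` places anchors at local minima of a lightly smoothed curve
in the valleys between the known reflections (one anchor per ~3°, range
endpoints pinned) and interpolates a natural cubic spline — the amorphous
halo model. A two-Gaussian `broad_halo` alternative sits behind a flag.
`fitPeaks()` then runs Levenberg–Marquardt least squares of pseudo-Voigt
profiles on the background-subtracted signal, co-fitting a local linear term
that absorbs the residual mismatch of the smooth background under the peaks
(without it, fitted FWHMs inflate by ~10%). `analyzeDiffractogram()` adds
one refinement round — the background is refit on the peak-subtracted
signal, removing the bias that Lorentzian peak tails impose on the anchors —
and reports Eq.-style crystallinity (trapezoidal areas on the native grid,
clamped to [0, 100]), Bragg spacings d = 2π/q with q = 4π sin θ/λ, and
Scherrer sizes τ = Kλ/(β cos θ) with K = 0.94, β the FWHM in radians.
No instrumental-broadening correction is applied (a user-supplied instrument
width can be subtracted in quadrature upstream if known). Recovery on
synthetic patterns at 10/20/30% true fractions is within ~1.5 points.

Quadrature is performed against the 2θ abscissa (the crystallinity range is
quoted in 2θ), and angles are degrees at interfaces, radians internally.

# Raman preprocessing and the carbonyl test

`preprocessSpectrum()` applies Savitzky–Golay smoothing of polynomial degree
7 — the customary 12-point window is even, so the nearest odd width (13) is
used and recorded in the processing log — followed by piecewise polynomial
background subtraction (degree 8 over 256-point windows, 50% overlap,
raised-cosine blending at seams) and normalization to the strongest
cellulose band at 1094 cm⁻¹. Subtraction precedes normalization; a
polynomial background of degree ≥ 1 makes the result invariant to linear
baseline injection (asserted at ≤ 2% RMS; in practice the change is at
floating-point level). Every step is logged and reprocessing a processed
spectrum is rejected; normalization is idempotent.

`detectBand()` scores a candidate band — by default the acetylation C=O
stretch near 1740 cm⁻¹, whose absence indicates deacetylated cellulose — as
(window maximum − flank mean)/noise SD and declares presence at score ≥ 3.
The noise SD comes from first differences of the flanking regions (8×
half-width on each side), which is insensitive to slow baseline drift; this
estimator keeps the Monte-Carlo false-positive rate of the threshold-3 rule
at ~3% on flat-noise spectra, within the ≤ 5% calibration the package
asserts. The threshold is a package choice; the underlying observation in
real spectra is visual absence.

# Tensile analysis

`loadCurve()` crops the raw displacement–force record at the first sample
reaching the 2.5 mN minimum onset, re-zeroes displacement there, and
converts to engineering strain (over the 20 mm starting grip spacing, used
as gauge length — crosshead displacement, no extensometer) and engineering
stress (force over width × measured thickness; default dogbone width 2 mm).
`tensileModulus()` is the least-squares slope between 60% and 80% of the
strain at maximum stress (≥ 5 samples required, reported otherwise).
`tensileStrength()` reports the maximum stress before rupture; rupture is
the first sample where stress falls below half the running maximum within 3
samples of that maximum, ignoring drops while the running maximum is still
below 10% of the record's peak (noise in the toe is not rupture). Curves
without a detected rupture are flagged, and both the maximum stress and the
stress at the last pre-rupture sample are reported (identical for an abrupt
rupture). `genTensileCurve()` provides the matching truth: a quadratic toe
joining the linear branch with continuous slope, exact linear modulus, and
an abrupt drop at the requested strength.

# Equivalent-cylinder density

`segmentCrossSection()` thresholds the side-view photograph with Otsu's
method (manual override available), keeps the largest connected component
and converts pixel count to mm². `pellicleDensity()` applies the
equivalent-cylinder model: h = A/(2r) with r the container radius (a
required input — it is a property of the culture vessel, not the image),
V = πr²h, ρ = W/V in mg/cm³. The density is invariant to the photograph's
pixel scale by construction. The scale (mm per pixel) is an explicit input;
detecting a scale bar in the photograph is out of scope.

# Statistics

`anovaGroups()` wraps `stats::aov` for one- and two-way fixed-effects ANOVA
(interaction included for two factors, sequential sums of squares with a
warning when unbalanced; empty cells are an error naming the cell). The
degenerate all-identical input is reported as F = 0, p = 1.
`bonferroniPairwise()` is gated on the omnibus p < 0.05; all level pairs are
then tested with pooled-variance t statistics using the ANOVA residual mean
square, p-values are multiplied by the number of pairs and capped at 1, and
stars follow the 0.05/0.01/0.001 convention. Under a simulated 4-group null
the omnibus type-I error sits at its nominal 5% and the gated family-wise
error below it. `pearsonR()` wraps `stats::cor` with explicit degenerate-
input errors.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run on reduced problem sizes
chosen to keep the full suite in minutes on one core while leaving every
conclusion unchanged: fiber stacks of ~80 × 18 px at radiality magnification
5 (13 nm subpixels — four times finer than the 100 nm floor) with 100
frames and 30 stacks per recovery estimate; detector frames just large
enough to accept 2θ = 48°; 10 seeds per WAXS fraction; 1000 replicates for
the statistical calibration. The paper-scale settings (512 × 512 frames,
magnification 10) run through the same code path unchanged.

Other numerical conventions: trapezoidal quadrature on native grids;
linear interpolation of half-maximum crossings; Catmull–Rom interpolation
for subpixel sampling; all generators are bit-deterministic given a seed;
flat peak plateaus are assigned their center sample; ties at the median
prominence are retained.
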