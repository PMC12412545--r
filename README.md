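# pellimetrics

Quantitative characterization of bacterial cellulose at the fiber and
pellicle scale.

Cellulose-producing bacteria (*Komagataeibacter* spp.) grow macroscopic
pellicles of entangled cellulose fibers. Each fiber alternates ordered
(crystalline) and disordered (amorphous) domains; the pellicle's network
density governs its mechanics. Comparing strains therefore needs the same
measurements, reproducibly, at several scales — and that is what this
package implements, for microscopists and materials scientists working with
bacterial cellulose:

* **Single-fiber crystallinity from fluorescence.** Blinking-fluorophore
  TIRF timelapses of dye-stained fibers are reconstructed by
  super-resolution radial fluctuations (SRRF): per-frame radiality maps
  R(x) scoring local gradient convergence on a magnified grid, combined over
  time by the order-2 temporal radiality auto-correlation (TRAC),
  with image-based drift correction. Intensity profiles along traced fibers
  are segmented into bright (amorphous) peaks — filtered by FWHM ≥ 100 nm,
  spacing ≥ 100 nm and a per-fiber median-prominence cut — and dark
  (crystalline) gaps, giving

  crystallinity% = Σ dark lengths / (Σ dark + Σ bright lengths) × 100.

* **Pellicle crystallinity from WAXS.** 2D detector frames are merged
  (slit-eraser), azimuthally integrated to I(2θ), decomposed into an
  amorphous background (anchor spline) plus pseudo-Voigt reflections, and
  scored over 2θ ∈ [10°, 45°] by

  crystallinity% = (area_sample − area_background) / area_sample × 100,

  with lattice spacings d = 2π/q (Bragg, first order) and crystallite sizes
  τ = Kλ/(β cos θ) (Scherrer, K = 0.94).

* **Raman preprocessing** (Savitzky–Golay, piecewise polynomial background,
  normalization at 1094 cm⁻¹) with a calibrated presence test for the
  acetylation carbonyl band near 1740 cm⁻¹.

* **Tensile mechanics** of wet dogbone specimens: 2.5 mN onset shift,
  engineering stress–strain, modulus from the 60–80% window of the strain at
  maximum stress, strength at rupture.

* **Equivalent-cylinder density**: side-view photo segmentation (Otsu),
  h = A/(2r), V = πr²h, ρ = W/V.

* **Group statistics**: one/two-way ANOVA, Bonferroni-corrected pairwise
  t tests gated on the omnibus result, Pearson correlation.

Every input has a seed-deterministic synthetic generator with stored ground
truth (`genFiberStack`, `genDiffractogram`, `genDetectorImage`,
`genTensileCurve`, `genPelliclePhoto`), so the complete pipeline is testable
without instrument data.

## Worked example

Simulate one stained fiber with exactly 75% crystallinity, image it for 100
frames, and run the full reconstruction + segmentation pipeline:

```r
library(pellimetrics)

ft <- fiberTruth(rep(c("crystalline", "amorphous"), 5), rep(c(600, 200), 5))
ft
#> GroundTruthFiber: 10 domains, total 4000 nm, crystallinity 75.0%

stack <- genFiberStack(ft, n_frames = 100, seed = 1)
stack
#> FiberStack: 100 frames of 77x18 px, 247 emitters, truth 75.0%

res <- analyzeFiberStack(stack, srrfParams(magnification = 5L))
res$segmentation
#> DomainSegmentation: 3 dark / 4 bright domains, crystallinity 73.1%

summarizeFibers(list(res$segmentation))
#>   dark_mean_nm dark_sd_nm bright_mean_nm bright_sd_nm crystallinity_mean_pct ...
#> 1     627.4674    9.14861       173.3241     4.879872               73.08317 ...
```

The measured dark (≈627 nm) and bright (≈173 nm) domain lengths recover the
simulated 600/200 nm structure, and the crystallinity lands within two
points of the 75% truth.

WAXS on a synthetic diffractogram with a 20% crystalline fraction:

```r
g <- genDiffractogram(patternTruth(0.20), seed = 1)
waxs <- analyzeDiffractogram(g$diffractogram)
waxs
#> CrystallinityResult: crystallinity 19.1% over [10, 45] deg; 5 peaks

peakTable(waxs)[, c("label", "center_deg", "fwhm_deg", "d_A", "tau_nm")]
#>   label center_deg  fwhm_deg      d_A   tau_nm
#> 1  1-10   14.90189 0.9865560 5.937815 8.478755
#> 2   110   16.69454 1.0015684 5.304033 8.369816
#> 3   012   20.49819 1.2221782 4.327592 6.896399
#> 4   200   22.90117 0.9042014 3.878650 9.359169
#> 5   004   34.51031 1.3404297 2.595848 6.479282
```

The 200 reflection at 22.9° gives a 3.88 Å lattice spacing and a 9.4 nm
crystallite size — the range expected for cellulose I.

Mechanics and density from their generators:

```r
gt <- genTensileCurve(10, 1.5, toe_strain = 0.03, noise_sd_MPa = 0.01, seed = 1)
cv <- loadCurve(gt$displacement_mm, gt$force_N, gt$geometry)
tensileModulus(cv)              # 9.980624  (truth 10 MPa)
tensileStrength(cv)$strength_MPa  # 1.510086  (truth 1.5 MPa)

ph <- genPelliclePhoto(20, 5, 0.1, seed = 1)
sg <- segmentCrossSection(ph$photo, ph$scale_mm_per_px)
pellicleDensity(sg$area_mm2, 20, 31.416)
#> PellicleGeometry: A 200.0 mm^2, r 20.0 mm, h 5.00 mm, rho 5 mg/cm^3
```

See `vignettes/pellimetrics-methods.Rmd` for the models, parameter choices
and known limitations.

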