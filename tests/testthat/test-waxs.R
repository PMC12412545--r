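# WAXS reduction: slit merge, azimuthal integration, background and peak
# fits, crystallinity index, Bragg spacings, Scherrer sizes.

test_that("slit merge averages unmasked pixels and flags double-masked ones", {
  a <- matrix(2, 10, 10); b <- matrix(4, 10, 10)
  m <- mergeLineEraser(a, b)
  expect_true(all(m$frame == 3))
  expect_false(any(m$mask))

  # identical frames with empty masks reproduce the input
  m2 <- mergeLineEraser(a, a)
  expect_equal(m2$frame, a)

  # complementary slit masks leave no invalid pixels
  ma <- matrix(FALSE, 10, 10); ma[4:5, ] <- TRUE
  mb <- matrix(FALSE, 10, 10); mb[8, ] <- TRUE
  m3 <- mergeLineEraser(a, b, ma, mb)
  expect_false(any(m3$mask))
  expect_true(all(m3$frame[4:5, ] == 4))
  expect_true(all(m3$frame[8, ] == 2))

  # doubly masked pixels are invalid
  mc <- matrix(FALSE, 10, 10); mc[1, 1] <- TRUE
  m4 <- mergeLineEraser(a, b, mc, mc)
  expect_true(m4$mask[1, 1])
  expect_true(is.na(m4$frame[1, 1]))
  expect_error(mergeLineEraser(a, matrix(0, 5, 5)), "shapes")
})

test_that("azimuthal integration matches the per-pixel binning oracle", {
  geo <- detectorGeometry(distance_mm = 20)
  # small synthetic ring frame at 2-theta 22.7 degrees
  pat <- diffractogram1D(seq(1, 35, 0.1),
                         100 * exp(-(seq(1, 35, 0.1) - 22.7)^2 / (2 * 0.5^2)) + 5)
  det <- genDetectorImage(pat, geo, seed = 1, dim = c(301, 301))
  d <- integrateAzimuthal(det$frame, det$geometry, n_bins = 120,
                          range_deg = c(2, 33))
  oracle <- bruteForceIntegrate(det$frame, det$geometry, 120, c(2, 33))
  ok <- !is.na(oracle) & !is.na(intensityValues(d))
  expect_gt(mean(ok), 0.9)
  expect_equal(intensityValues(d)[ok], oracle[ok], tolerance = 1e-9)
  # the ring lands in the right bin
  pk_tt <- twoTheta(d)[which.max(intensityValues(d))]
  expect_lt(abs(pk_tt - 22.7), diff(twoTheta(d)[1:2]) + 1e-9)
})

test_that("integration of a uniform frame is flat and rotation-invariant", {
  geo <- detectorGeometry(distance_mm = 20)
  fr <- matrix(10, 301, 301)
  d <- integrateAzimuthal(fr, geo, n_bins = 100, range_deg = c(3, 35))
  y <- intensityValues(d)
  inner <- y[5:95]
  expect_lt(sd(inner, na.rm = TRUE) / mean(inner, na.rm = TRUE), 0.01)

  set.seed(5)
  fr2 <- matrix(10 + rnorm(301^2), 301, 301)
  d1 <- integrateAzimuthal(fr2, geo, n_bins = 100, range_deg = c(3, 35))
  d2 <- integrateAzimuthal(t(fr2)[, 301:1], geo, n_bins = 100,
                           range_deg = c(3, 35))  # 90-degree rotation
  r <- intensityValues(d1) / intensityValues(d2)
  expect_true(all(abs(r - 1) < 0.005, na.rm = TRUE))
  expect_error(integrateAzimuthal(fr, geo, n_bins = 100,
                                  mask = matrix(TRUE, 301, 301)), "masked")
})

test_that("background fit tracks a peak-free halo and a zero background", {
  g <- genDiffractogram(patternTruth(0), seed = 2)
  bg <- fitBackground(g$diffractogram)
  expect_lt(abs(crystallinityIndex(g$diffractogram, bg)), 2)

  # peaks only (Gaussian, so tails die off), zero halo: background area small
  peaks <- cbind(center_deg = c(14.9, 16.7, 20.5, 22.9, 34.5),
                 fwhm_deg = c(1, 1, 1.2, 0.9, 1.4),
                 area = c(60, 75, 25, 120, 20), eta = 0)
  pt <- new("GroundTruthPattern", peaks = peaks,
            halo = cbind(center_deg = 20, sigma_deg = 7, amplitude = 0),
            noise_sd = 0.2, crystalline_fraction = 1)
  g2 <- genDiffractogram(pt, seed = 2)
  bg2 <- fitBackground(g2$diffractogram)
  x <- twoTheta(g2$diffractogram); sel <- x >= 10 & x <= 45
  a_s <- pellimetrics:::.trapz(x[sel], intensityValues(g2$diffractogram)[sel])
  expect_lt(bg2@area_background / a_s, 0.03)

  # adding a constant raises the background area by about c * range width
  g3 <- genDiffractogram(patternTruth(0.2), seed = 4)
  bg3 <- fitBackground(g3$diffractogram)
  d4 <- diffractogram1D(twoTheta(g3$diffractogram),
                        intensityValues(g3$diffractogram) + 50)
  bg4 <- fitBackground(d4)
  expect_equal(bg4@area_background - bg3@area_background, 50 * 35,
               tolerance = 0.05 * 50 * 35)
})

test_that("pseudo-Voigt peak fitting recovers generator peaks", {
  # single noiseless Gaussian with exact init
  x <- seq(8, 48, 0.05)
  y <- pellimetrics:::.pseudoVoigt(x, 120, 22.9, 0.8, 0)
  d <- diffractogram1D(x, y)
  bg0 <- new("BackgroundFit", model = "anchor_spline", anchors_deg = numeric(0),
             background = rep(0, length(x)), range_deg = c(10, 45),
             area_background = 0)
  pf <- fitPeaks(d, bg0, init_centers_deg = 22.9, init_fwhm_deg = 0.8)
  expect_true(pf@converged)
  expect_equal(peakTable(pf)$center_deg, 22.9, tolerance = 1e-6)
  expect_equal(peakTable(pf)$fwhm_deg, 0.8, tolerance = 1e-6)

  # two overlapping generator peaks: centers within 0.05 deg, FWHM within 5%
  pt <- patternTruth(0.35, peak_centers_deg = c(20.5, 22.9),
                     peak_fwhm_deg = c(1.0, 0.9), peak_rel_area = c(0.45, 0.55),
                     peak_eta = c(0.3, 0.3), noise_sd = 0.3)
  g <- genDiffractogram(pt, seed = 6)
  bg <- fitBackground(g$diffractogram, peak_centers_deg = c(20.5, 22.9))
  pf2 <- fitPeaks(g$diffractogram, bg, init_centers_deg = c(20.5, 22.9))
  pk <- peakTable(pf2)
  truth <- pt@peaks
  for (i in seq_len(nrow(truth))) {
    j <- which.min(abs(pk$center_deg - truth[i, "center_deg"]))
    expect_lt(abs(pk$center_deg[j] - truth[i, "center_deg"]), 0.05)
    expect_lt(abs(pk$fwhm_deg[j] - truth[i, "fwhm_deg"]) / truth[i, "fwhm_deg"],
              0.05)
  }

  # basin stability: init 0.3 degrees off lands on the same solution
  pf3 <- fitPeaks(g$diffractogram, bg,
                  init_centers_deg = pt@peaks[, "center_deg"] + 0.3)
  expect_equal(sort(peakTable(pf3)$center_deg), sort(pk$center_deg),
               tolerance = 1e-3)
})

test_that("crystallinity index satisfies its closed-form limits", {
  x <- seq(8, 48, 0.05)
  y <- 100 * exp(-(x - 21)^2 / (2 * 8^2)) + 10
  d <- diffractogram1D(x, y)
  zero_bg <- new("BackgroundFit", model = "anchor_spline",
                 anchors_deg = numeric(0), background = rep(0, length(x)),
                 range_deg = c(10, 45), area_background = 0)
  expect_equal(crystallinityIndex(d, zero_bg), 100)
  sel <- x >= 10 & x <= 45
  full_bg <- new("BackgroundFit", model = "anchor_spline",
                 anchors_deg = numeric(0), background = y,
                 range_deg = c(10, 45),
                 area_background = pellimetrics:::.trapz(x[sel], y[sel]))
  expect_equal(crystallinityIndex(d, full_bg), 0)
  # invariance to uniform rescaling
  g <- genDiffractogram(patternTruth(0.2), seed = 8)
  bgf <- fitBackground(g$diffractogram)
  c1 <- crystallinityIndex(g$diffractogram, bgf)
  d2 <- diffractogram1D(twoTheta(g$diffractogram),
                        7 * intensityValues(g$diffractogram))
  bg2 <- new("BackgroundFit", model = bgf@model, anchors_deg = bgf@anchors_deg,
             background = 7 * bgf@background, range_deg = bgf@range_deg,
             area_background = 7 * bgf@area_background)
  expect_equal(crystallinityIndex(d2, bg2), c1, tolerance = 1e-9)
})

test_that("Bragg and Scherrer conversions match hand arithmetic", {
  expect_equal(braggSpacing(2 * pi), 1, tolerance = 1e-12)
  expect_equal(braggSpacing(1), 6.283185, tolerance = 1e-6)
  # 2-theta 22.7 deg, lambda 1.54 A
  q <- twoThetaToQ(22.7, 1.54)
  expect_equal(braggSpacing(q), 1.54 / (2 * sin(11.35 * pi / 180)),
               tolerance = 1e-12)
  expect_equal(braggSpacing(q), 3.913, tolerance = 1e-3)
  expect_error(braggSpacing(0), "q must be")

  # theta = 0 limit: beta 0.0154 rad -> tau = 0.94 * 1.54 / 0.0154 A = 9.4 nm
  beta_deg <- 0.0154 * 180 / pi
  expect_equal(scherrerSize(beta_deg, 0), 9.4, tolerance = 1e-9)
  # doubling beta halves tau exactly
  expect_equal(scherrerSize(2 * beta_deg, 0), 9.4 / 2, tolerance = 1e-12)
  # 22.7 deg center, beta 0.6 deg
  tau <- scherrerSize(0.6, 22.7)
  oracle <- 0.94 * 1.54 / ((0.6 * pi / 180) * cos(11.35 * pi / 180)) / 10
  expect_equal(tau, oracle, tolerance = 1e-12)
  expect_equal(tau, 14.1, tolerance = 0.05)
  expect_error(scherrerSize(0.6, 365), "cos")
})

test_that("Bragg spacing is strictly decreasing in scattering angle", {
  tts <- seq(1, 89, by = 0.5)
  ds <- braggSpacing(twoThetaToQ(tts, 1.54))
  expect_true(all(diff(ds) < 0))
})

test_that("full diffractogram analysis report is internally consistent", {
  g <- genDiffractogram(patternTruth(0.25), seed = 10)
  res <- analyzeDiffractogram(g$diffractogram)
  expect_s4_class(res, "CrystallinityResult")
  pk <- peakTable(res)
  expect_true(all(pk$d_A > 0) && all(pk$tau_nm > 0))
  expect_equal(pk$d_A, braggSpacing(twoThetaToQ(pk$center_deg, 1.54)),
               tolerance = 1e-12)
  # Scherrer on the generator's known FWHM reproduces tau exactly
  beta <- g$truth@peaks[, "fwhm_deg"]; ctr <- g$truth@peaks[, "center_deg"]
  tau <- scherrerSize(beta, ctr)
  expect_equal(scherrerSize(beta, ctr), tau, tolerance = 1e-9)
})
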