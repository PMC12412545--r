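# Profile extraction, the three peak filters and Eq.-style domain
# segmentation.

test_that("profile extraction averages correctly on simple geometries", {
  img <- matrix(3.7, 40, 60)
  tr <- cbind(x = c(5, 55), y = c(20, 20))
  prof <- extractProfile(img, tr, pixel_size_nm = 100, width_nm = 1000,
                         step_nm = 50)
  expect_true(all(abs(profileIntensities(prof) - 3.7) < 1e-9))

  # vertical bright stripe crossed by a horizontal trace
  img2 <- matrix(0, 40, 60); img2[, 30:32] <- 5
  prof2 <- extractProfile(img2, tr, pixel_size_nm = 100, width_nm = 600,
                          step_nm = 25)
  x <- profilePositions(prof2); y <- profileIntensities(prof2)
  # stripe center at x = 31 px -> 26 px from trace start -> 2600 nm
  expect_lt(abs(x[which.max(y)] - 2600), 150)

  expect_error(extractProfile(img, cbind(c(-3, 10), c(5, 5)), 100), "leaves")
})

test_that("widening the averaging width preserves a uniform background mean", {
  set.seed(7)
  img <- matrix(rnorm(60 * 80, mean = 10), 60, 80)
  tr <- cbind(x = c(10, 70), y = c(30, 30))
  p1 <- extractProfile(img, tr, 100, width_nm = 1000, step_nm = 100)
  p2 <- extractProfile(img, tr, 100, width_nm = 2000, step_nm = 100)
  expect_equal(mean(profileIntensities(p1)), mean(profileIntensities(p2)),
               tolerance = 0.02)
  # doubling the transverse averaging width reduces the noise variance
  expect_lt(var(profileIntensities(p2)), var(profileIntensities(p1)))
})

test_that("flat profiles yield empty peak sets, not errors", {
  prof <- intensityProfile(seq(0, 2000, 50), rep(1, 41))
  ps <- findPeaksFiltered(prof)
  expect_equal(nrow(peakTable(ps)), 0L)
})

test_that("median-prominence cut keeps the stronger of two unequal peaks", {
  x <- seq(0, 4000, by = 20)
  y <- 10 * exp(-(x - 1200)^2 / (2 * 120^2)) + 3 * exp(-(x - 2800)^2 / (2 * 120^2))
  prof <- intensityProfile(x, y)
  ps <- findPeaksFiltered(prof)
  pk <- peakTable(ps)
  # median of prominences {10, 3} is 6.5; only the 10-peak survives
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$position_nm - 1200), 40)
  expect_equal(ps@median_prominence, 6.5, tolerance = 0.05)
})

test_that("equal-prominence peaks are all retained (ties at the median)", {
  x <- seq(0, 4800, by = 20)
  y <- numeric(length(x))
  for (ctr in c(800, 2400, 4000)) y <- y + exp(-(x - ctr)^2 / (2 * 120^2))
  ps <- findPeaksFiltered(intensityProfile(x, y))
  expect_equal(nrow(peakTable(ps)), 3L)
})

test_that("filtered peaks match the exhaustive brute-force enumerator", {
  set.seed(123)
  for (rep in 1:40) {
    n <- sample(16:64, 1)
    step <- sample(c(40, 60, 80), 1)
    x <- seq(0, by = step, length.out = n)
    y <- as.numeric(stats::filter(rnorm(n + 6), rep(1 / 3, 3), sides = 2))[4:(n + 3)]
    y[is.na(y)] <- 0
    got <- peakTable(findPeaksFiltered(intensityProfile(x, y)))
    want <- bruteForcePeaks(x, y)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$position_nm, want$position_nm)
      expect_equal(got$fwhm_nm, want$fwhm_nm, tolerance = 1e-12)
      expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
    }
  }
})

test_that("domain segmentation computes the length-based crystallinity", {
  # two peaks of FWHM 200 nm at 800-nm spacing on a smooth two-bump profile
  x <- seq(0, 2000, by = 10)
  y <- exp(-(x - 600)^2 / (2 * 85^2)) + exp(-(x - 1400)^2 / (2 * 85^2))
  seg <- segmentDomains(intensityProfile(x, y),
                        findPeaksFiltered(intensityProfile(x, y)))
  expect_equal(length(brightLengths(seg)), 2L)
  expect_equal(length(darkLengths(seg)), 1L)
  cr <- crystallinity(seg)
  expect_equal(cr, 100 * sum(darkLengths(seg)) /
                 (sum(darkLengths(seg)) + sum(brightLengths(seg))),
               tolerance = 1e-9)
  expect_true(cr >= 0 && cr <= 100)

  # dark 600/600, bright 200/200 arithmetic = 75%
  seg2 <- new("DomainSegmentation", bright_lengths_nm = c(200, 200),
              dark_lengths_nm = c(600, 600), crystallinity_pct = 75)
  expect_equal(crystallinity(seg2), 75)

  # square wave, period 800 nm, 50% duty -> crystallinity 50 +- 1
  ftsq <- fiberTruth(rep(c("crystalline", "amorphous"), 5), rep(400, 10),
                     psf_sigma_px = 0.2)
  g <- genIntensityProfile(ftsq, step_nm = 10, noise_sd = 0, seed = 1)
  segsq <- segmentDomains(g$profile, findPeaksFiltered(g$profile))
  expect_equal(crystallinity(segsq), 50, tolerance = 1)

  expect_error(segmentDomains(g$profile,
                              new("PeakSet", peaks = peakTable(findPeaksFiltered(g$profile))[1, ],
                                  median_prominence = 1, min_fwhm_nm = 100,
                                  min_spacing_nm = 100)),
               "insufficient")
})

test_that("fiber summaries pool domains and average crystallinity", {
  s1 <- new("DomainSegmentation", bright_lengths_nm = c(200, 180),
            dark_lengths_nm = c(570), crystallinity_pct = 60)
  s2 <- new("DomainSegmentation", bright_lengths_nm = c(150, 210),
            dark_lengths_nm = c(640), crystallinity_pct = 64)
  sm <- summarizeFibers(list(s1, s2))
  expect_equal(sm$crystallinity_mean_pct, 62)
  expect_equal(sm$crystallinity_sd_pct, sd(c(60, 64)))
  expect_equal(sm$n_fibers, 2)
  expect_equal(sm$n_peaks, 4)
  expect_equal(sm$dark_mean_nm, mean(c(570, 640)))
  sm1 <- summarizeFibers(list(s1))
  expect_equal(sm1$crystallinity_mean_pct, 60)
  expect_error(summarizeFibers(list()), "no segmentations")
  # two fibers at 70 and 80 percent average to 75 +- SD 7.071
  s3 <- new("DomainSegmentation", bright_lengths_nm = 300,
            dark_lengths_nm = c(350, 350), crystallinity_pct = 70)
  s4 <- new("DomainSegmentation", bright_lengths_nm = 200,
            dark_lengths_nm = c(400, 400), crystallinity_pct = 80)
  sm2 <- summarizeFibers(list(s3, s4))
  expect_equal(sm2$crystallinity_mean_pct, 75)
  expect_equal(sm2$crystallinity_sd_pct, 7.071, tolerance = 1e-3)
})

test_that("no retained domain is shorter than the resolution floor", {
  ok <- 0
  for (s in 1:5) {
    ft <- randomFiberTruth(n_pairs = 5, seed = s)
    g <- genIntensityProfile(ft, step_nm = 10, noise_sd = 0.03, seed = s)
    prof <- smoothProfile(g$profile, 40)
    seg <- try(segmentDomains(prof, findPeaksFiltered(prof)), silent = TRUE)
    if (inherits(seg, "try-error")) next
    ok <- ok + 1
    expect_true(all(brightLengths(seg) >= 100))
  }
  expect_gte(ok, 3)
})

test_that("estimated crystallinity increases with the true fraction", {
  # amorphous lengths stay above the 100 nm resolution floor throughout, and
  # crystalline domains flank the fiber so every amorphous domain is interior
  # (the stretches beyond the outermost peaks are discarded by design)
  fracs <- seq(0.45, 0.85, length.out = 20)
  mest <- numeric(0)
  for (i in seq_along(fracs)) {
    f <- fracs[i]
    period <- 800
    ft <- fiberTruth(c("crystalline", rep(c("amorphous", "crystalline"), 16)),
                     c(period * f, rep(c(period * (1 - f), period * f), 16)),
                     psf_sigma_px = 0.5)
    vals <- numeric(0)
    for (s in 1:5) {
      g <- genIntensityProfile(ft, step_nm = 10, noise_sd = 0.02,
                               seed = 1000 * i + s)
      prof <- smoothProfile(g$profile, 40)
      seg <- try(segmentDomains(prof, findPeaksFiltered(prof)), silent = TRUE)
      if (!inherits(seg, "try-error")) vals <- c(vals, crystallinity(seg))
    }
    mest <- c(mest, mean(vals))
  }
  expect_false(anyNA(mest))
  expect_gt(cor(fracs, mest, method = "spearman"), 0.9)
})
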