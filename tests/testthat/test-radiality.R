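# SRRF radiality maps, TRAC temporal combination and drift correction.

test_that("radiality vanishes on a constant frame and peaks on an emitter", {
  p <- srrfParams(magnification = 5L, drift_correction = FALSE)
  cc <- radialityMap(matrix(7, 16, 16), p)
  expect_lt(max(abs(cc)), 1e-6)

  em <- c(11.3, 10.6)  # (x, y), off-grid on purpose
  fr <- outer(seq_len(21), seq_len(21), function(y, x)
    exp(-((x - em[1])^2 + (y - em[2])^2) / (2 * 1.5^2)))
  m <- radialityMap(fr, p)
  pk <- arrayInd(which.max(m), dim(m))
  expect_lt(abs(pk[2] - ((em[1] - 0.5) * 5 + 0.5)), 1)
  expect_lt(abs(pk[1] - ((em[2] - 0.5) * 5 + 0.5)), 1)
})

test_that("radiality agrees with a brute-force convergence score", {
  em <- c(11.3, 10.6)
  fun <- function(x, y) exp(-((x - em[1])^2 + (y - em[2])^2) / (2 * 1.5^2))
  fr <- outer(seq_len(21), seq_len(21), function(y, x) fun(x, y))
  p <- srrfParams(magnification = 5L, intensity_weighting = FALSE,
                  drift_correction = FALSE)
  m <- radialityMap(fr, p)
  # compare at a handful of subpixels around the emitter; the oracle is
  # evaluated at the exact center coordinate of each compared subpixel
  for (dx in c(-0.4, 0, 0.6)) for (dy in c(-0.6, 0, 0.4)) {
    i <- round((em[2] + dy - 0.5) * 5 + 0.5)
    j <- round((em[1] + dx - 0.5) * 5 + 0.5)
    cx <- (j - 0.5) / 5 + 0.5; cy <- (i - 0.5) / 5 + 0.5
    oracle <- bruteForceRadiality(fun, cx, cy)
    # interpolated-grid gradients versus analytic gradients: agreement on
    # the radiality scale (max 1), not to high relative precision
    expect_lt(abs(m[i, j] - oracle), 0.1)
  }
})

test_that("radiality is invariant to a constant intensity offset", {
  em <- c(11.3, 10.6)
  fr <- outer(seq_len(21), seq_len(21), function(y, x)
    exp(-((x - em[1])^2 + (y - em[2])^2) / (2 * 1.5^2)))
  p <- srrfParams(magnification = 5L, intensity_weighting = FALSE,
                  drift_correction = FALSE)
  m1 <- radialityMap(fr, p)
  m2 <- radialityMap(fr + 100, p)
  expect_lt(max(abs(m2 - m1)) / max(abs(m1)), 1e-5)
})

test_that("TRAC of a temporally constant stack is the squared radiality map", {
  fr <- outer(seq_len(16), seq_len(16), function(y, x)
    exp(-((x - 8.2)^2 + (y - 9.1)^2) / 6)) + 0.1
  st <- array(rep(fr, 4), dim = c(16, 16, 4))
  p <- srrfParams(magnification = 3L, drift_correction = FALSE)
  out <- tracReconstruct(st, p)
  expect_equal(out, pmax(radialityMap(fr, p), 0)^2, tolerance = 1e-12)
  expect_error(tracReconstruct(array(fr, dim = c(16, 16, 1)), p), "2 frames")
})

test_that("independently blinking emitters give two TRAC maxima", {
  e1 <- c(6.5, 8.5); e2 <- c(14.5, 9.5)
  set.seed(42)
  st <- array(0, dim = c(18, 20, 30))
  for (t in 1:30) {
    img <- matrix(0.05, 18, 20)
    if (runif(1) < 0.5)
      img <- img + outer(seq_len(18), seq_len(20), function(y, x)
        exp(-((x - e1[1])^2 + (y - e1[2])^2) / (2 * 1.2^2)))
    if (runif(1) < 0.5)
      img <- img + outer(seq_len(18), seq_len(20), function(y, x)
        exp(-((x - e2[1])^2 + (y - e2[2])^2) / (2 * 1.2^2)))
    st[, , t] <- img
  }
  p <- srrfParams(magnification = 3L, drift_correction = FALSE)
  out <- tracReconstruct(st, p)
  pk1 <- arrayInd(which.max(out), dim(out))
  # silence the first emitter's neighborhood, the second must remain
  masked <- out
  r1 <- (e1[2] - 0.5) * 3 + 0.5; c1 <- (e1[1] - 0.5) * 3 + 0.5
  masked[abs(row(out) - r1) < 9 & abs(col(out) - c1) < 9] <- 0
  pk2 <- arrayInd(which.max(masked), dim(masked))
  found <- rbind(pk1, pk2)
  want <- rbind(c((e1[2] - 0.5) * 3 + 0.5, (e1[1] - 0.5) * 3 + 0.5),
                c((e2[2] - 0.5) * 3 + 0.5, (e2[1] - 0.5) * 3 + 0.5))
  d <- function(a, b) sqrt(sum((a - b)^2))
  expect_lt(min(d(found[1, ], want[1, ]), d(found[1, ], want[2, ])), 2.5)
  expect_lt(min(d(found[2, ], want[1, ]), d(found[2, ], want[2, ])), 2.5)
})

test_that("lag-free TRAC variant is invariant to frame permutation", {
  ft <- smallFiberTruth(2)
  st <- genFiberStack(ft, n_frames = 6, seed = 3)
  p <- srrfParams(magnification = 2L, trac_lag = 0L, drift_correction = FALSE)
  a <- tracReconstruct(st@frames, p)
  b <- tracReconstruct(st@frames[, , c(4, 1, 6, 2, 5, 3)], p)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("drift correction recovers an imposed integer drift", {
  base <- outer(seq_len(40), seq_len(40), function(y, x)
    exp(-((x - 20)^2 + (y - 17)^2) / 10)) + 0.1
  st <- array(0, dim = c(40, 40, 4))
  for (t in 1:4) {
    sh <- t - 1  # 1 px/frame in x
    img <- matrix(0.1, 40, 40)
    img[, (1 + sh):40] <- base[, 1:(40 - sh)]
    st[, , t] <- img
  }
  dc <- driftCorrect(st)
  expect_equal(dc$drift[, "dx"], c(0, 1, 2, 3), tolerance = 0.25)
  expect_equal(dc$drift[, "dy"], rep(0, 4), tolerance = 0.25)
  # round trip: interior of corrected frames matches the static image
  expect_equal(dc$stack[5:35, 5:35, 4], base[5:35, 5:35], tolerance = 1e-6)
  # static stack -> zero shifts
  st0 <- array(rep(base, 3), dim = c(40, 40, 3))
  expect_true(all(driftCorrect(st0)$drift == 0))
})

test_that("reconstruction does not widen a point emitter", {
  p <- srrfParams(magnification = 3L, drift_correction = FALSE)
  for (s in 1:10) {
    set.seed(s)
    em <- c(8 + runif(1, -0.5, 0.5), 8 + runif(1, -0.5, 0.5))
    st <- array(0, dim = c(15, 15, 12))
    for (t in 1:12) {
      on <- rbinom(1, 1, 0.7)
      st[, , t] <- 0.05 + on * outer(seq_len(15), seq_len(15), function(y, x)
        exp(-((x - em[1])^2 + (y - em[2])^2) / (2 * 1.3^2)))
    }
    rec <- tracReconstruct(st, p)
    mean_img <- apply(st, c(1, 2), mean)
    ri <- round((em[2] - 0.5) * 3 + 0.5)
    fw_rec <- profileFWHM(seq_len(ncol(rec)) / 3, rec[ri, ])
    fw_raw <- profileFWHM(seq_len(15), mean_img[round(em[2]), ])
    expect_lte(fw_rec, fw_raw)
  }
})

test_that("non-finite pixels are rejected", {
  fr <- matrix(1, 10, 10); fr[3, 3] <- NA
  expect_error(radialityMap(fr, srrfParams(magnification = 2L)), "non-finite")
})
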