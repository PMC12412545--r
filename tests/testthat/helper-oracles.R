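# Independent brute-force oracles used to validate the implementation.
# These are deliberately written as plain exhaustive loops, separate from the
# package's algorithms.

# Exhaustive peak enumerator applying the same three filters as
# findPeaksFiltered: local maxima with topographic prominence, FWHM at half
# of (height - local inter-peak base), minimum FWHM, minimum spacing
# (dropping the less prominent of the closest violating pair), and the
# median-prominence cut (ties retained).
bruteForcePeaks <- function(x, y, min_fwhm = 100, min_spacing = 100) {
  n <- length(y)
  # plateau-aware local maxima
  peaks <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[j]) j <- j + 1L
      if (j < n && y[j + 1L] < y[j]) peaks <- c(peaks, as.integer(floor((i + j) / 2)))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(peaks) == 0) return(data.frame(position_nm = numeric(0)))
  prom <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; h <- y[p]
    higher_l <- which(y[seq_len(p - 1L)] > h)
    sL <- if (length(higher_l)) min(y[max(higher_l):p]) else min(y[1:p])
    higher_r <- p + which(y[(p + 1L):n] > h)
    sR <- if (length(higher_r) && p < n) min(y[p:min(higher_r)]) else min(y[p:n])
    prom[k] <- h - max(sL, sR)
  }
  base <- fwhm <- lh <- rh <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    lmin <- if (k == 1L) min(y[1:p]) else min(y[peaks[k - 1L]:p])
    rmin <- if (k == length(peaks)) min(y[p:n]) else min(y[p:peaks[k + 1L]])
    base[k] <- max(lmin, rmin)
    half <- base[k] + (y[p] - base[k]) / 2
    j <- p
    while (j > 1L && y[j - 1L] > half) j <- j - 1L
    lh[k] <- if (j == 1L) x[1] else {
      fr <- (y[j] - half) / (y[j] - y[j - 1L]); x[j] - fr * (x[j] - x[j - 1L])
    }
    j <- p
    while (j < n && y[j + 1L] > half) j <- j + 1L
    rh[k] <- if (j == n) x[n] else {
      fr <- (y[j] - half) / (y[j] - y[j + 1L]); x[j] + fr * (x[j + 1L] - x[j])
    }
    fwhm[k] <- rh[k] - lh[k]
  }
  df <- data.frame(position_nm = x[peaks], height = y[peaks],
                   prominence = prom, fwhm_nm = fwhm)
  df <- df[df$fwhm_nm >= min_fwhm, , drop = FALSE]
  repeat {
    if (nrow(df) < 2) break
    gaps <- diff(df$position_nm)
    viol <- which(gaps < min_spacing)
    if (length(viol) == 0) break
    b <- viol[which.min(gaps[viol])]
    kill <- if (df$prominence[b] <= df$prominence[b + 1]) b else b + 1L
    df <- df[-kill, , drop = FALSE]
  }
  if (nrow(df) > 0) {
    medp <- median(df$prominence)
    df <- df[df$prominence >= medp, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# Brute-force radiality score of one point: sample gradients of the image
# function (numeric central differences with a tiny step) at ring points and
# score line convergence directly.
bruteForceRadiality <- function(fun, cx, cy, ring_radius = 0.5, axes = 8) {
  h <- 1e-4
  score <- 0
  for (k in seq_len(axes)) {
    a <- 2 * pi * (k - 1) / axes
    px <- cx + ring_radius * cos(a); py <- cy + ring_radius * sin(a)
    gx <- (fun(px + h, py) - fun(px - h, py)) / (2 * h)
    gy <- (fun(px, py + h) - fun(px, py - h)) / (2 * h)
    gn <- sqrt(gx^2 + gy^2)
    if (gn < 1e-12) next
    vx <- cx - px; vy <- cy - py
    dist <- abs(gx * vy - gy * vx) / gn
    s <- sign(gx * vx + gy * vy)
    score <- score + s * max(0, 1 - dist / ring_radius)
  }
  score / axes
}

# Per-pixel azimuthal binning oracle: mean intensity per equal-width
# 2-theta bin computed with explicit loops over pixels.
bruteForceIntegrate <- function(frame, geometry, n_bins, range_deg) {
  ny <- nrow(frame); nx <- ncol(frame)
  bc <- geometry@beam_center_px
  if (any(is.na(bc))) bc <- c((nx + 1) / 2, (ny + 1) / 2)
  px_mm <- geometry@pixel_size_um / 1000
  edges <- seq(range_deg[1], range_deg[2], length.out = n_bins + 1)
  sums <- cnts <- numeric(n_bins)
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    v <- frame[iy, ix]
    if (!is.finite(v)) next
    r <- sqrt((ix - bc[1])^2 + (iy - bc[2])^2) * px_mm
    tt <- atan(r / geometry@distance_mm) * 180 / pi
    b <- findInterval(tt, edges, rightmost.closed = TRUE)
    if (b >= 1 && b <= n_bins) { sums[b] <- sums[b] + v; cnts[b] <- cnts[b] + 1 }
  }
  ifelse(cnts > 0, sums / cnts, NA_real_)
}

# FWHM of a vector profile by linear interpolation at half its maximum
# (above its minimum); used for resolution comparisons.
profileFWHM <- function(x, y) {
  y <- y - min(y)
  p <- which.max(y)
  half <- y[p] / 2
  j <- p; while (j > 1 && y[j - 1] > half) j <- j - 1
  xl <- if (j == 1) x[1] else {
    f <- (y[j] - half) / (y[j] - y[j - 1]); x[j] - f * (x[j] - x[j - 1])
  }
  j <- p; while (j < length(y) && y[j + 1] > half) j <- j + 1
  xr <- if (j == length(y)) x[length(x)] else {
    f <- (y[j] - half) / (y[j] - y[j + 1]); x[j] + f * (x[j + 1] - x[j])
  }
  xr - xl
}

# Synthetic cellulose-like Raman spectrum on a fixed grid.
ramanFixture <- function(baseline = 0, noise_sd = 0.5, seed = 1,
                         carbonyl_amp = 0) {
  wn <- seq(200, 3200, by = 1.5)
  set.seed(seed)
  y <- 50 * exp(-(wn - 1094)^2 / (2 * 8^2)) +
    20 * exp(-(wn - 1120)^2 / (2 * 9^2)) +
    15 * exp(-(wn - 380)^2 / (2 * 7^2)) +
    25 * exp(-(wn - 2894)^2 / (2 * 12^2)) +
    carbonyl_amp * exp(-(wn - 1740)^2 / (2 * 8^2)) +
    baseline + rnorm(length(wn), sd = noise_sd)
  ramanSpectrum(wn, y)
}

# Small fiber truth used across tests (75% crystallinity, paper-like scale).
smallFiberTruth <- function(n_pairs = 5)
  fiberTruth(rep(c("crystalline", "amorphous"), n_pairs),
             rep(c(600, 200), n_pairs))
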