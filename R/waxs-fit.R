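# Amorphous background fitting, pseudo-Voigt peak fitting and the derived
# crystallinity index, Bragg spacings and Scherrer crystallite sizes.

# light running-mean smoothing over approximately `span_deg` degrees
.smoothCurve <- function(x, y, span_deg = 0.5) {
  step <- stats::median(diff(x))
  half <- max(1L, round(span_deg / step / 2))
  k <- rep(1 / (2 * half + 1), 2 * half + 1)
  padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(padded, k, sides = 2))[half + seq_along(y)]
}

#' Fit the amorphous background of a diffractogram
#'
#' Selects anchor points in the valleys between the known crystalline
#' reflections (local minima of a lightly smoothed curve, away from the peak
#' windows) and draws a natural cubic spline through them; the result is a
#' smooth curve lying at or below the signal at the anchors, taken as the
#' amorphous halo. A two-component broad-halo fit is available as an
#' alternative model.
#'
#' @param d a \code{\link{diffractogram1D}}.
#' @param range_deg integration range, default c(10, 45).
#' @param peak_centers_deg known reflection positions to avoid when placing
#'   anchors; defaults to the packaged cellulose I-beta table.
#' @param exclusion_halfwidth_deg half-width of the exclusion window around
#'   each reflection.
#' @param model \code{"anchor_spline"} (default) or \code{"broad_halo"} (sum
#'   of two wide Gaussians fitted to the anchor regions).
#' @return A \code{BackgroundFit}.
#' @export
fitBackground <- function(d, range_deg = c(10, 45),
                          peak_centers_deg = celluloseIbetaPeaks()$twotheta_deg,
                          exclusion_halfwidth_deg = 1.8,
                          model = c("anchor_spline", "broad_halo")) {
  stopifnot(is(d, "Diffractogram1D"))
  model <- match.arg(model)
  xfull <- twoTheta(d)
  ok <- is.finite(intensityValues(d))
  x <- xfull[ok]; y <- intensityValues(d)[ok]
  if (min(x) > range_deg[1] || max(x) < range_deg[2])
    stop("integration range lies outside the diffractogram grid")
  inr <- x >= range_deg[1] & x <= range_deg[2]
  xs <- x[inr]; ys <- .smoothCurve(x[inr], y[inr])
  near_peak <- rep(FALSE, length(xs))
  for (p in peak_centers_deg)
    near_peak <- near_peak | abs(xs - p) < exclusion_halfwidth_deg
  # contiguous valley regions; one anchor (the local minimum) per ~3 degrees
  free <- which(!near_peak)
  if (length(free) == 0) stop("no anchor candidates outside the peak windows")
  brk <- c(0, which(diff(free) > 1), length(free))
  anchors <- integer(0)
  for (i in seq_len(length(brk) - 1)) {
    idx <- free[(brk[i] + 1):brk[i + 1]]
    width <- xs[idx[length(idx)]] - xs[idx[1]]
    nsub <- max(1L, floor(width / 3))
    grp <- ceiling(seq_along(idx) * nsub / length(idx))
    for (sub in split(idx, grp)) anchors <- c(anchors, sub[which.min(ys[sub])])
  }
  # pin the range endpoints so the spline cannot run away
  anchors <- sort(unique(c(anchors, 1L, length(xs))))
  if (length(anchors) < 4) stop("fewer than 4 background anchor candidates")
  ax <- xs[anchors]; ay <- ys[anchors]
  if (model == "anchor_spline") {
    f <- splinefun(ax, ay, method = "natural")
    bg_full <- f(xfull)
  } else {
    start <- c(a1 = max(ay), c1 = 20, s1 = 7, a2 = max(ay) / 4, c2 = 38, s2 = 6)
    res_fn <- function(p)
      ay - (p[1] * exp(-(ax - p[2])^2 / (2 * p[3]^2)) +
              p[4] * exp(-(ax - p[5])^2 / (2 * p[6]^2)))
    fit <- minpack.lm::nls.lm(start, fn = res_fn,
                              lower = c(0, 5, 1, 0, 5, 1),
                              upper = c(Inf, 60, 30, Inf, 60, 30))
    p <- fit$par
    bg_full <- p[1] * exp(-(xfull - p[2])^2 / (2 * p[3]^2)) +
      p[4] * exp(-(xfull - p[5])^2 / (2 * p[6]^2))
  }
  bg_full <- pmax(bg_full, 0)
  sel <- ok & xfull >= range_deg[1] & xfull <= range_deg[2]
  new("BackgroundFit", model = model, anchors_deg = ax, background = bg_full,
      range_deg = as.numeric(range_deg),
      area_background = .trapz(xfull[sel], bg_full[sel]))
}

# sum of pseudo-Voigt peaks; par = c(heights, centers, fwhms, etas)
.pvSum <- function(x, par, npk) {
  h <- par[seq_len(npk)]
  ctr <- par[npk + seq_len(npk)]
  w <- par[2 * npk + seq_len(npk)]
  eta <- par[3 * npk + seq_len(npk)]
  out <- numeric(length(x))
  for (i in seq_len(npk)) out <- out + .pseudoVoigt(x, h[i], ctr[i], w[i], eta[i])
  out
}

#' Fit pseudo-Voigt peaks to a background-subtracted diffractogram
#'
#' Nonlinear least squares (Levenberg-Marquardt) of a sum of pseudo-Voigt
#' profiles on intensity minus fitted background. A local linear term is
#' co-fitted by default to absorb the residual mismatch of the smooth
#' background model under the peaks. Non-convergence is flagged in the
#' result, never silently ignored.
#'
#' @param d a \code{\link{diffractogram1D}}.
#' @param bg a \code{\link{fitBackground}} result.
#' @param init_centers_deg initial peak centers; defaults to the packaged
#'   cellulose I-beta reflections inside the background range.
#' @param init_fwhm_deg initial FWHM for every peak.
#' @param labels optional Miller labels attached to the peaks.
#' @param linear_term co-fit a linear residual-background term (default TRUE).
#' @return A \code{PeakFit}.
#' @export
fitPeaks <- function(d, bg, init_centers_deg = NULL, init_fwhm_deg = 1,
                     labels = NULL, linear_term = TRUE) {
  stopifnot(is(d, "Diffractogram1D"), is(bg, "BackgroundFit"))
  if (is.null(init_centers_deg)) {
    ref <- celluloseIbetaPeaks()
    keep <- ref$twotheta_deg > bg@range_deg[1] & ref$twotheta_deg < bg@range_deg[2]
    init_centers_deg <- ref$twotheta_deg[keep]
    if (is.null(labels)) labels <- ref$label[keep]
  }
  if (any(init_centers_deg <= bg@range_deg[1] | init_centers_deg >= bg@range_deg[2]))
    stop("initial centers must lie inside the background range")
  x <- twoTheta(d); y <- intensityValues(d)
  ok <- is.finite(y)
  x <- x[ok]; yres <- (y - bg@background)[ok]
  sel <- x >= bg@range_deg[1] & x <= bg@range_deg[2]
  x <- x[sel]; yres <- yres[sel]
  npk <- length(init_centers_deg)
  h0 <- vapply(init_centers_deg,
               function(ctr) max(c(yres[abs(x - ctr) < 1], 1e-6), na.rm = TRUE),
               numeric(1))
  start <- c(h0, init_centers_deg, rep(init_fwhm_deg, npk), rep(0.3, npk))
  lower <- c(rep(0, npk), init_centers_deg - 2, rep(0.05, npk), rep(0, npk))
  upper <- c(rep(Inf, npk), init_centers_deg + 2, rep(6, npk), rep(1, npk))
  xmid <- mean(bg@range_deg)
  if (linear_term) {
    start <- c(start, 0, 0)
    lower <- c(lower, -Inf, -Inf)
    upper <- c(upper, Inf, Inf)
  }
  resid_fn <- function(p) {
    yhat <- .pvSum(x, p, npk)
    if (linear_term)
      yhat <- yhat + p[4 * npk + 1] + p[4 * npk + 2] * (x - xmid)
    yres - yhat
  }
  fit <- minpack.lm::nls.lm(start, fn = resid_fn, lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 400))
  p <- fit$par
  peaks <- data.frame(center_deg = p[npk + seq_len(npk)],
                      height = p[seq_len(npk)],
                      fwhm_deg = p[2 * npk + seq_len(npk)],
                      eta = p[3 * npk + seq_len(npk)])
  if (!is.null(labels)) peaks$label <- labels
  conv <- fit$info %in% 1:3
  if (!conv)
    warning("peak fit did not converge: ", fit$message)
  new("PeakFit", peaks = peaks,
      baseline = if (linear_term) p[4 * npk + 1:2] else c(0, 0),
      converged = conv, message = as.character(fit$message))
}

#' Area-based crystallinity index of a diffractogram
#'
#' crystallinity\% = 100 * (area_sample - area_background) / area_sample with
#' both areas computed by trapezoidal quadrature on the same grid over the
#' background's range (default 10-45 degrees); the result is clamped to
#' [0, 100].
#'
#' @param d a \code{\link{diffractogram1D}}.
#' @param bg a \code{\link{fitBackground}} result on the same grid.
#' @return Percentage in [0, 100].
#' @export
crystallinityIndex <- function(d, bg) {
  stopifnot(is(d, "Diffractogram1D"), is(bg, "BackgroundFit"))
  x <- twoTheta(d); y <- intensityValues(d)
  if (length(bg@background) != length(x))
    stop("background was fitted on a different grid")
  ok <- is.finite(y)
  sel <- ok & x >= bg@range_deg[1] & x <= bg@range_deg[2]
  area_sample <- .trapz(x[sel], y[sel])
  if (area_sample == 0) stop("sample area is zero; crystallinity undefined")
  area_bg <- .trapz(x[sel], bg@background[sel])
  min(max(100 * (area_sample - area_bg) / area_sample, 0), 100)
}

#' Bragg lattice spacing from the scattering vector
#'
#' First-order Bragg spacing d = 2 pi / q.
#'
#' @param q_invA scattering vector (1/Angstrom), > 0.
#' @return Spacing in Angstrom.
#' @examples
#' braggSpacing(twoThetaToQ(22.7, 1.54))
#' @export
braggSpacing <- function(q_invA) {
  if (any(q_invA <= 0)) stop("q must be > 0")
  2 * pi / q_invA
}

#' Scherrer crystallite size from peak broadening
#'
#' tau = K * lambda / (beta * cos(theta)) with beta the FWHM in radians and
#' theta half the scattering angle; reported in nanometers.
#'
#' @param fwhm_deg peak FWHM in degrees 2-theta.
#' @param center_deg peak center in degrees 2-theta.
#' @param wavelength_A wavelength in Angstrom (default 1.54).
#' @param K shape factor (default 0.94).
#' @return Crystallite size in nm.
#' @examples
#' scherrerSize(0.6, 22.7)
#' @export
scherrerSize <- function(fwhm_deg, center_deg, wavelength_A = 1.54, K = 0.94) {
  if (any(fwhm_deg <= 0)) stop("FWHM must be > 0")
  theta <- center_deg / 2 * pi / 180
  if (any(cos(theta) <= 0)) stop("cos(theta) must be > 0")
  beta <- fwhm_deg * pi / 180
  K * wavelength_A / (beta * cos(theta)) / 10
}

#' Full WAXS analysis of a 1D diffractogram
#'
#' Fits the amorphous background, computes the area-based crystallinity index
#' over the 10-45 degree window, fits pseudo-Voigt peaks and derives Bragg
#' lattice spacings and Scherrer crystallite sizes per reflection.
#'
#' @param d a \code{\link{diffractogram1D}}.
#' @param range_deg integration range (default c(10, 45)).
#' @param init_centers_deg initial peak centers (default: packaged cellulose
#'   I-beta table).
#' @param K Scherrer shape factor.
#' @param refine_background refit the background on the peak-subtracted
#'   signal once (default TRUE); this removes the bias that peak tails
#'   otherwise impose on the anchor points.
#' @param ... further arguments to \code{\link{fitBackground}}.
#' @return A \code{CrystallinityResult}.
#' @export
analyzeDiffractogram <- function(d, range_deg = c(10, 45),
                                 init_centers_deg = NULL, K = 0.94,
                                 refine_background = TRUE, ...) {
  bg <- fitBackground(d, range_deg = range_deg, ...)
  pf <- fitPeaks(d, bg, init_centers_deg = init_centers_deg)
  if (refine_background) {
    pk0 <- peakTable(pf)
    ysub <- intensityValues(d) -
      .pvSum(twoTheta(d), c(pk0$height, pk0$center_deg, pk0$fwhm_deg, pk0$eta),
             nrow(pk0))
    dsub <- diffractogram1D(twoTheta(d), ysub, d@wavelength_A)
    bg <- fitBackground(dsub, range_deg = range_deg, ...)
    pf <- fitPeaks(d, bg, init_centers_deg = init_centers_deg)
  }
  x <- twoTheta(d); y <- intensityValues(d)
  sel <- is.finite(y) & x >= range_deg[1] & x <= range_deg[2]
  area_sample <- .trapz(x[sel], y[sel])
  pct <- crystallinityIndex(d, bg)
  pk <- peakTable(pf)
  pk$q_invA <- twoThetaToQ(pk$center_deg, d@wavelength_A)
  pk$d_A <- braggSpacing(pk$q_invA)
  pk$tau_nm <- scherrerSize(pk$fwhm_deg, pk$center_deg, d@wavelength_A, K)
  new("CrystallinityResult", area_sample = area_sample,
      area_background = bg@area_background, crystallinity_pct = pct,
      range_deg = as.numeric(range_deg), peaks = pk)
}
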