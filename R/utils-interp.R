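# Separable Catmull-Rom (bicubic) interpolation on a regular pixel grid,
# expressed as dense weight matrices so that evaluating a whole magnified
# grid is two matrix products: B = Wr %*% A %*% t(Wc).

# Catmull-Rom kernel weights for fractional offset s in [0,1), acting on
# samples at knots {-1, 0, 1, 2} relative to floor(u).
.cubicW <- function(s) {
  cbind(-0.5 * s^3 + s^2 - 0.5 * s,
        1.5 * s^3 - 2.5 * s^2 + 1,
        -1.5 * s^3 + 2 * s^2 + 0.5 * s,
        0.5 * s^3 - 0.5 * s^2)
}

# d/du of the same weights (grid spacing 1); used for analytic gradients of
# the interpolated field.
.cubicDW <- function(s) {
  cbind(-1.5 * s^2 + 2 * s - 0.5,
        4.5 * s^2 - 5 * s,
        -4.5 * s^2 + 4 * s + 0.5,
        1.5 * s^2 - s)
}

# Weight matrix mapping n samples (1-based integer centers) to values of the
# interpolant at coordinates u (any positions, clamped at the borders).
# deriv = TRUE gives the first derivative of the interpolant instead.
.interpWeights <- function(u, n, deriv = FALSE) {
  j0 <- floor(u)
  s <- u - j0
  W4 <- if (deriv) .cubicDW(s) else .cubicW(s)
  out <- matrix(0, length(u), n)
  for (k in 0:3) {
    idx <- pmin(pmax(j0 - 1 + k, 1L), n)
    out[cbind(seq_along(u), idx)] <- out[cbind(seq_along(u), idx)] + W4[, k + 1]
  }
  out
}

# Coordinates (in units of the original 1-based pixel grid) of the centers of
# the magnified subpixels: subpixel I covers [(I-1)/M, I/M) of original pixel
# space with pixel centers at integers.
.magCoords <- function(n, M) {
  (seq_len(n * M) - 0.5) / M + 0.5
}

# Bilinear sampling of a matrix at arbitrary (row, col) positions, clamped.
# The shape of `r` (vector or matrix) is preserved in the result.
.bilinear <- function(A, r, cc) {
  dm <- dim(r)
  r <- as.vector(r); cc <- as.vector(cc)
  nr <- nrow(A); nc <- ncol(A)
  r <- pmin(pmax(r, 1), nr)
  cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  out <- A[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    A[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    A[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    A[cbind(r0 + 1, c0 + 1)] * fr * fc
  if (!is.null(dm)) dim(out) <- dm
  out
}

# Pseudo-Voigt profile parameterized by height, center, FWHM and Lorentzian
# mixing eta in [0,1].
.pseudoVoigt <- function(x, height, center, fwhm, eta) {
  u <- (x - center) / fwhm
  g <- exp(-4 * log(2) * u^2)
  l <- 1 / (1 + 4 * u^2)
  height * (eta * l + (1 - eta) * g)
}

# Integrated area of a pseudo-Voigt over the real line.
.pseudoVoigtArea <- function(height, fwhm, eta) {
  height * fwhm * (eta * pi / 2 + (1 - eta) * 0.5 * sqrt(pi / log(2)))
}

# Trapezoidal quadrature.
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

.stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}
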