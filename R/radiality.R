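# Super-resolution radial fluctuations: per-frame radiality maps on a
# magnified subpixel grid, combined over time by temporal radiality
# auto-correlation (TRAC), with optional image-based drift correction.

# Cache of weight matrices for one frame geometry: for every required
# (offset, deriv) pair along rows and columns.
.makeWeights <- function(ny, nx, M, offsets_r, offsets_c) {
  ur <- .magCoords(ny, M); uc <- .magCoords(nx, M)
  key <- function(o, d) sprintf("%.10f|%d", o, d)
  Wr <- new.env(); Wc <- new.env()
  getW <- function(env, u, n, o, d) {
    k <- key(o, d)
    if (is.null(env[[k]])) env[[k]] <- .interpWeights(u + o, n, deriv = d)
    env[[k]]
  }
  list(row = function(o, d = FALSE) getW(Wr, ur, ny, o, d),
       col = function(o, d = FALSE) getW(Wc, uc, nx, o, d))
}

#' Radiality map of a single frame
#'
#' For every subpixel of the magnified grid, intensity gradients are sampled
#' at points on a ring of radius \code{ring_radius_px} around the subpixel
#' center and scored by how closely the gradient line through each ring point
#' passes the center (converging gradients score high, diverging ones count
#' negatively). Gradients are the analytic derivatives of the bicubic
#' (Catmull-Rom) interpolant of the frame. With intensity weighting enabled
#' the map is multiplied by the interpolated intensity.
#'
#' @param frame numeric matrix (rows y, columns x), at least 8x8, finite.
#' @param params an \code{\link{srrfParams}} object.
#' @return Radiality matrix of size \code{dim(frame) * magnification}.
#' @export
radialityMap <- function(frame, params = srrfParams()) {
  stopifnot(is(params, "SRRFParams"))
  if (nrow(frame) < 8 || ncol(frame) < 8) stop("frame must be at least 8x8")
  .stopIfNotFinite(frame, "frame")
  M <- params@magnification
  r <- params@ring_radius_px
  K <- params@axes
  ny <- nrow(frame); nx <- ncol(frame)
  W <- .makeWeights(ny, nx, M, NULL, NULL)
  ang <- 2 * pi * (seq_len(K) - 1) / K
  acc <- matrix(0, ny * M, nx * M)
  for (k in seq_len(K)) {
    dx <- r * cos(ang[k]); dy <- r * sin(ang[k])
    # gradient of the interpolated field at the ring points
    gx <- W$row(dy) %*% frame %*% t(W$col(dx, TRUE))
    gy <- W$row(dy, TRUE) %*% frame %*% t(W$col(dx))
    gnorm <- sqrt(gx^2 + gy^2)
    # vector from ring point to subpixel center is (-dx, -dy)
    dist <- abs(gx * dy - gy * dx) / pmax(gnorm, .Machine$double.eps)
    conv <- sign(-(gx * dx + gy * dy))
    contrib <- conv * pmax(0, 1 - dist / r)
    # gradients far below the dominant gradient scale (or below the
    # floating-point noise of the image values) carry no reliable
    # orientation information
    thr <- max(1e-6 * max(gnorm), 1e-12 * max(abs(frame), 1e-300))
    contrib[gnorm < thr] <- 0
    acc <- acc + contrib
  }
  acc <- acc / K
  if (params@intensity_weighting) {
    I0 <- W$row(0) %*% frame %*% t(W$col(0))
    acc <- acc * I0
  }
  acc
}

#' Image-based drift correction of a timelapse
#'
#' Registers every frame to the first by the translation maximizing the
#' FFT cross-correlation, refined to subpixel precision by a parabolic fit
#' around the correlation peak, and resamples frames bilinearly.
#'
#' @param stack numeric array (y, x, t), at least 2 frames.
#' @return A list with \code{stack} (corrected array) and \code{drift}
#'   (t x 2 matrix of applied (dx, dy) shifts in px).
#' @export
driftCorrect <- function(stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2) stop("need an array with at least 2 frames")
  ref <- stack[, , 1]
  Fref <- Conj(fft(ref))
  ny <- d[1]; nx <- d[2]
  drift <- matrix(0, d[3], 2, dimnames = list(NULL, c("dx", "dy")))
  out <- stack
  para <- function(m, c0, p) {
    # parabolic sub-sample refinement, guarded against flat neighborhoods
    denom <- m - 2 * c0 + p
    if (abs(denom) < 1e-12) 0 else 0.5 * (m - p) / denom
  }
  for (t in 2:d[3]) {
    fr <- stack[, , t]
    if (all(fr == 0)) {
      warning("all-zero frame ", t, "; zero shift assumed")
      next
    }
    cc <- Re(fft(fft(fr) * Fref, inverse = TRUE))
    pk <- arrayInd(which.max(cc), dim(cc))
    iy <- pk[1]; ix <- pk[2]
    wrap <- function(i, n) ((i - 1) %% n) + 1
    sy <- para(cc[wrap(iy - 1, ny), ix], cc[iy, ix], cc[wrap(iy + 1, ny), ix])
    sx <- para(cc[iy, wrap(ix - 1, nx)], cc[iy, ix], cc[iy, wrap(ix + 1, nx)])
    dy <- iy - 1 + sy; dx <- ix - 1 + sx
    if (dy > ny / 2) dy <- dy - ny
    if (dx > nx / 2) dx <- dx - nx
    # sub-nanometric refinements on a symmetric correlation are fp noise
    if (abs(dx) < 1e-6) dx <- 0
    if (abs(dy) < 1e-6) dy <- 0
    drift[t, ] <- c(dx, dy)
    if (dx != 0 || dy != 0) {
      gr <- matrix(seq_len(ny), ny, nx) + dy
      gc <- matrix(rep(seq_len(nx), each = ny), ny, nx) + dx
      out[, , t] <- .bilinear(fr, gr, gc)
    }
  }
  list(stack = out, drift = drift)
}

#' Temporal radiality auto-correlation (TRAC) reconstruction
#'
#' Computes the per-frame radiality maps of a timelapse, clips negative
#' (divergent) radiality to zero, and combines the time series per subpixel
#' by the order-2 auto-correlation: the mean of pairwise products of
#' consecutive frames (\code{trac_lag = 1}), or the mean square
#' (\code{trac_lag = 0}, invariant to frame order).
#'
#' @param stack numeric array (y, x, t) with at least 2 frames.
#' @param params an \code{\link{srrfParams}}; drift correction is applied
#'   here when enabled.
#' @return The reconstructed super-resolved matrix
#'   (\code{dim(frame) * magnification}).
#' @export
tracReconstruct <- function(stack, params = srrfParams()) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] < 2)
    stop("degenerate input: TRAC needs at least 2 frames")
  nt <- d[3]
  lag <- params@trac_lag
  acc <- NULL
  prev <- NULL
  for (t in seq_len(nt)) {
    cur <- pmax(radialityMap(stack[, , t], params), 0)
    if (lag == 0L) {
      acc <- if (is.null(acc)) cur^2 else acc + cur^2
    } else if (!is.null(prev)) {
      acc <- if (is.null(acc)) prev * cur else acc + prev * cur
    }
    prev <- cur
  }
  acc / (nt - lag)
}

#' SRRF reconstruction of a fluorescence timelapse
#'
#' The full pipeline: optional drift correction, per-frame radiality on the
#' magnified grid, temporal combination by TRAC.
#'
#' @param stack numeric array (y, x, t) or a \code{FiberStack}.
#' @param params an \code{\link{srrfParams}} object.
#' @return A list with \code{image} (the reconstruction), \code{drift}
#'   (t x 2 shift matrix, zeros when correction is off) and \code{params}.
#' @examples
#' ft <- fiberTruth(c("crystalline", "amorphous"), c(600, 200))
#' st <- genFiberStack(ft, n_frames = 4, seed = 1)
#' rec <- srrfReconstruct(st, srrfParams(magnification = 2L))
#' dim(rec$image)
#' @export
srrfReconstruct <- function(stack, params = srrfParams()) {
  if (is(stack, "FiberStack")) stack <- stack@frames
  d <- dim(stack)
  drift <- matrix(0, d[3], 2, dimnames = list(NULL, c("dx", "dy")))
  if (params@drift_correction) {
    dc <- driftCorrect(stack)
    stack <- dc$stack
    drift <- dc$drift
  }
  list(image = tracReconstruct(stack, params), drift = drift, params = params)
}
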