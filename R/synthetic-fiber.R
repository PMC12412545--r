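#' Synthetic blinking-fiber image stack
#'
#' Holds a generated fluorescence timelapse together with the ground truth it
#' was rendered from: frames are background plus stochastically blinking
#' Gaussian emitters placed only in the amorphous (dye-stained) domains of the
#' fiber; crystalline domains stay dark.
#'
#' @slot frames numeric array (rows y, columns x, frames t).
#' @slot truth the \code{GroundTruthFiber} used.
#' @slot trace_px the resolved fiber polyline (x, y) in pixels.
#' @slot emitters matrix (x, y) of emitter positions in pixels.
#' @export
setClass("FiberStack", representation(
  frames = "array", truth = "GroundTruthFiber", trace_px = "matrix",
  emitters = "matrix"))

setMethod("show", "FiberStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("FiberStack: %d frames of %dx%d px, %d emitters, truth %.1f%%\n",
              d[3], d[2], d[1], nrow(object@emitters),
              100 * trueCrystallinity(object@truth)))
})

# Lay a fiber out horizontally, centered vertically, with a safety margin.
.autoPath <- function(truth) {
  L_px <- sum(truth@lengths_nm) / truth@pixel_size_nm
  margin <- ceiling(4 * truth@psf_sigma_px) + 3
  ny <- 2 * margin + 7
  y0 <- (ny + 1) / 2
  cbind(x = c(margin + 1, margin + 1 + L_px), y = c(y0, y0))
}

# Cumulative arclength (px) of a polyline.
.polylineArclength <- function(path) {
  seg <- sqrt(rowSums(diff(path)^2))
  c(0, cumsum(seg))
}

# Point on the polyline at arclength s (px).
.polylinePoint <- function(path, s) {
  arc <- .polylineArclength(path)
  s <- pmin(pmax(s, 0), max(arc))
  i <- findInterval(s, arc, rightmost.closed = TRUE)
  i <- pmin(i, nrow(path) - 1L)
  f <- (s - arc[i]) / pmax(arc[i + 1] - arc[i], .Machine$double.eps)
  path[i, , drop = FALSE] + (path[i + 1L, , drop = FALSE] - path[i, , drop = FALSE]) * f
}

# Draw emitter arclength positions (nm) for a fiber truth: a Poisson process
# at emitter_density_um in amorphous domains and density / contrast_ratio in
# crystalline ones (zero for the default infinite contrast).
.drawEmitters <- function(truth) {
  bounds <- c(0, cumsum(truth@lengths_nm))
  pos <- numeric(0)
  for (i in seq_along(truth@states)) {
    dens <- truth@emitter_density_um
    if (truth@states[i] == "crystalline") {
      dens <- if (is.infinite(truth@contrast_ratio)) 0 else dens / truth@contrast_ratio
    }
    lam <- dens * truth@lengths_nm[i] / 1000
    n <- if (lam > 0) rpois(1, lam) else 0L
    if (n > 0) pos <- c(pos, runif(n, bounds[i], bounds[i + 1]))
  }
  sort(pos)
}

#' Generate a blinking-fluorophore fiber timelapse
#'
#' Renders a synthetic TIRF timelapse of a single stained cellulose fiber.
#' Emitters are placed along the fiber path as a Poisson process restricted to
#' amorphous domains, blink independently per frame (Bernoulli with
#' \code{blink_prob}), and are rendered as Gaussian PSF spots. Noise is shot
#' noise (Poisson) on the expected photon image, or none.
#'
#' @param truth a \code{\link{fiberTruth}} object.
#' @param n_frames number of frames (>= 2; default 100).
#' @param seed integer seed; identical inputs and seed give identical stacks.
#' @param frame_dim optional c(ny, nx); derived from the path if omitted.
#' @param noise \code{"poisson"} (default) or \code{"none"}.
#' @return A \code{FiberStack}.
#' @examples
#' ft <- fiberTruth(rep(c("crystalline", "amorphous"), 3), rep(c(600, 200), 3))
#' st <- genFiberStack(ft, n_frames = 5, seed = 1)
#' st
#' @export
genFiberStack <- function(truth, n_frames = 100, seed = 1, frame_dim = NULL,
                          noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stopifnot(is(truth, "GroundTruthFiber"))
  if (n_frames < 2) stop("n_frames must be >= 2")
  set.seed(seed)
  path <- if (nrow(truth@path_px) >= 2) truth@path_px else .autoPath(truth)
  if (is.null(frame_dim)) {
    margin <- ceiling(4 * truth@psf_sigma_px) + 3
    frame_dim <- c(ceiling(max(path[, 2]) + margin),
                   ceiling(max(path[, 1]) + margin))
  }
  ny <- frame_dim[1]; nx <- frame_dim[2]
  m <- truth@psf_sigma_px
  if (any(path[, 1] < 1 + m) || any(path[, 1] > nx - m) ||
      any(path[, 2] < 1 + m) || any(path[, 2] > ny - m))
    stop("fiber path lies outside the frame (PSF margin violated)")

  pos_nm <- .drawEmitters(truth)
  em <- .polylinePoint(path, pos_nm / truth@pixel_size_nm)
  colnames(em) <- c("x", "y")

  sig <- truth@psf_sigma_px
  xs <- seq_len(nx); ys <- seq_len(ny)
  # per-emitter separable Gaussian footprints, precomputed once
  fx <- lapply(seq_len(nrow(em)), function(i)
    exp(-(xs - em[i, 1])^2 / (2 * sig^2)))
  fy <- lapply(seq_len(nrow(em)), function(i)
    exp(-(ys - em[i, 2])^2 / (2 * sig^2)))

  frames <- array(0, dim = c(ny, nx, n_frames))
  for (t in seq_len(n_frames)) {
    img <- matrix(truth@background, ny, nx)
    if (nrow(em) > 0) {
      on <- rbinom(nrow(em), 1, truth@blink_prob) == 1
      for (i in which(on))
        img <- img + truth@peak_intensity * (fy[[i]] %o% fx[[i]])
    }
    if (noise == "poisson") img[] <- rpois(length(img), img)
    frames[, , t] <- img
  }
  new("FiberStack", frames = frames, truth = truth, trace_px = path,
      emitters = em)
}

#' Generate a noisy fiber intensity profile directly
#'
#' Bypasses the imaging model: the profile is the indicator of the amorphous
#' domains blurred with the PSF, scaled to unit amplitude, sampled every
#' \code{step_nm}, with additive Gaussian noise. Useful for unit-testing the
#' peak detection and segmentation stages in isolation.
#'
#' @param truth a \code{\link{fiberTruth}}.
#' @param step_nm sampling step (> 0).
#' @param noise_sd Gaussian noise SD in units of the (unit) amplitude.
#' @param seed integer seed.
#' @return A list with elements \code{profile} (an
#'   \code{\link{intensityProfile}}) and \code{truth}.
#' @export
genIntensityProfile <- function(truth, step_nm = 10, noise_sd = 0.02, seed = 1) {
  stopifnot(is(truth, "GroundTruthFiber"), step_nm > 0)
  set.seed(seed)
  L <- sum(truth@lengths_nm)
  pos <- seq(0, L, by = step_nm)
  bounds <- c(0, cumsum(truth@lengths_nm))
  state_at <- truth@states[pmin(findInterval(pos, bounds,
                                             rightmost.closed = TRUE),
                                length(truth@states))]
  ind <- as.numeric(state_at == "amorphous")
  sigma_nm <- truth@psf_sigma_px * truth@pixel_size_nm
  if (sigma_nm > 0) {
    half <- ceiling(4 * sigma_nm / step_nm)
    kx <- (-half):half
    k <- exp(-(kx * step_nm)^2 / (2 * sigma_nm^2))
    k <- k / sum(k)
    padded <- c(rep(ind[1], half), ind, rep(ind[length(ind)], half))
    ind <- as.numeric(stats::filter(padded, k, sides = 2))[half + seq_along(pos)]
  }
  y <- ind + rnorm(length(pos), sd = noise_sd)
  list(profile = intensityProfile(pos, y, pixel_size_nm = truth@pixel_size_nm),
       truth = truth)
}
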