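# Synthetic WAXS patterns: crystalline pseudo-Voigt peaks on a broad
# Gaussian amorphous halo, with an exact area-based crystalline fraction.

# Evaluate noiseless pattern components on a grid.
.patternComponents <- function(truth, grid) {
  pk <- numeric(length(grid))
  if (nrow(truth@peaks) > 0) {
    for (i in seq_len(nrow(truth@peaks))) {
      p <- truth@peaks[i, ]
      h <- p[["area"]] / .pseudoVoigtArea(1, p[["fwhm_deg"]], p[["eta"]])
      pk <- pk + .pseudoVoigt(grid, h, p[["center_deg"]], p[["fwhm_deg"]], p[["eta"]])
    }
  }
  bg <- numeric(length(grid))
  if (nrow(truth@halo) > 0) {
    for (i in seq_len(nrow(truth@halo))) {
      hcomp <- truth@halo[i, ]
      bg <- bg + hcomp[["amplitude"]] *
        exp(-(grid - hcomp[["center_deg"]])^2 / (2 * hcomp[["sigma_deg"]]^2))
    }
  }
  list(peaks = pk, background = bg)
}

# Area-based crystalline fraction over [10, 45] by fine trapezoidal quadrature
# of the noiseless components.
.patternFraction <- function(peaks, halo) {
  truth0 <- new("GroundTruthPattern", peaks = peaks, halo = halo,
                noise_sd = 0, crystalline_fraction = 0.5)
  grid <- seq(10, 45, by = 0.005)
  comp <- .patternComponents(truth0, grid)
  ap <- .trapz(grid, comp$peaks)
  ab <- .trapz(grid, comp$background)
  if (ap + ab == 0) 0 else ap / (ap + ab)
}

#' Construct a WAXS pattern ground truth
#'
#' Builds a synthetic diffraction pattern with crystalline reflections at the
#' cellulose I-beta positions on a broad amorphous halo, scaled so that the
#' area fraction of the peaks over the 10-45 degree window equals
#' \code{crystalline_fraction} (stored value computed by fine quadrature of
#' the noiseless components).
#'
#' @param crystalline_fraction target area-based crystalline fraction.
#' @param peak_centers_deg,peak_fwhm_deg,peak_rel_area,peak_eta per-reflection
#'   centers, FWHMs, relative areas and pseudo-Voigt mixing.
#' @param halo_center_deg,halo_sigma_deg center and width of the amorphous
#'   halo (a Gaussian).
#' @param halo_amplitude halo amplitude in counts.
#' @param noise_sd Gaussian noise SD (counts) used by
#'   \code{\link{genDiffractogram}}.
#' @return A \code{GroundTruthPattern}.
#' @examples
#' pt <- patternTruth(0.25)
#' trueCrystallinity(pt)
#' @export
patternTruth <- function(crystalline_fraction = 0.25,
                         peak_centers_deg = c(14.9, 16.7, 20.5, 22.9, 34.5),
                         peak_fwhm_deg = c(1.0, 1.0, 1.2, 0.9, 1.4),
                         peak_rel_area = c(0.20, 0.25, 0.08, 0.40, 0.07),
                         peak_eta = rep(0.3, 5),
                         halo_center_deg = 20.5, halo_sigma_deg = 7.5,
                         halo_amplitude = 100, noise_sd = 1) {
  stopifnot(crystalline_fraction >= 0, crystalline_fraction < 1)
  halo <- cbind(center_deg = halo_center_deg, sigma_deg = halo_sigma_deg,
                amplitude = halo_amplitude)
  if (crystalline_fraction == 0 || length(peak_centers_deg) == 0) {
    peaks <- matrix(numeric(0), 0, 4,
                    dimnames = list(NULL, c("center_deg", "fwhm_deg", "area", "eta")))
    return(new("GroundTruthPattern", peaks = peaks, halo = halo,
               noise_sd = noise_sd,
               crystalline_fraction = .patternFraction(peaks, halo)))
  }
  rel <- peak_rel_area / sum(peak_rel_area)
  peaks <- cbind(center_deg = peak_centers_deg, fwhm_deg = peak_fwhm_deg,
                 area = rel, eta = peak_eta)
  # scale total peak area so the quadrature fraction hits the target
  truth0 <- new("GroundTruthPattern", peaks = peaks, halo = halo,
                noise_sd = noise_sd, crystalline_fraction = 0.5)
  grid <- seq(10, 45, by = 0.005)
  comp <- .patternComponents(truth0, grid)
  ap <- .trapz(grid, comp$peaks)
  ab <- .trapz(grid, comp$background)
  scale <- crystalline_fraction / (1 - crystalline_fraction) * ab / ap
  peaks[, "area"] <- peaks[, "area"] * scale
  new("GroundTruthPattern", peaks = peaks, halo = halo, noise_sd = noise_sd,
      crystalline_fraction = .patternFraction(peaks, halo))
}

#' Generate a 1D diffractogram from a pattern truth
#'
#' @param truth a \code{\link{patternTruth}}.
#' @param grid 2-theta sampling grid in degrees; must cover [10, 45].
#' @param seed integer seed for the additive Gaussian noise.
#' @param wavelength_A wavelength for the q axis.
#' @return A list with elements \code{diffractogram} (a
#'   \code{\link{diffractogram1D}}), \code{components} (noiseless peak and
#'   background curves) and \code{truth}.
#' @export
genDiffractogram <- function(truth, grid = seq(8, 48, by = 0.05), seed = 1,
                             wavelength_A = 1.54) {
  stopifnot(is(truth, "GroundTruthPattern"))
  if (min(grid) > 10 || max(grid) < 45)
    stop("grid must cover at least [10, 45] degrees")
  set.seed(seed)
  comp <- .patternComponents(truth, grid)
  y <- comp$peaks + comp$background +
    if (truth@noise_sd > 0) rnorm(length(grid), sd = truth@noise_sd) else 0
  list(diffractogram = diffractogram1D(grid, y, wavelength_A),
       components = comp, truth = truth)
}

#' Generate a 2D detector frame from a 1D pattern
#'
#' Renders an isotropic flat-detector frame whose azimuthal integration
#' reproduces the given 1D pattern: every pixel gets the pattern intensity at
#' its scattering angle, plus Gaussian noise. A horizontal slit band can be
#' masked to emulate detector module gaps for merge tests.
#'
#' @param pattern a \code{Diffractogram1D} (e.g. from
#'   \code{\link{genDiffractogram}}).
#' @param geometry a \code{\link{detectorGeometry}}.
#' @param seed integer seed.
#' @param dim optional c(ny, nx) frame size; by default just large enough to
#'   accept the pattern's maximum angle.
#' @param noise_sd Gaussian noise SD (counts).
#' @param slit_rows optional integer c(first, last): rows masked as a slit.
#' @return A list with \code{frame} (matrix), \code{mask} (logical matrix,
#'   TRUE = masked) and \code{geometry} (with the beam center resolved).
#' @export
genDetectorImage <- function(pattern, geometry = detectorGeometry(), seed = 1,
                             dim = NULL, noise_sd = 0, slit_rows = NULL) {
  stopifnot(is(pattern, "Diffractogram1D"), is(geometry, "DetectorGeometry"))
  set.seed(seed)
  tt_max <- max(twoTheta(pattern))
  px_mm <- geometry@pixel_size_um / 1000
  if (tt_max >= 90)
    stop("pattern range exceeds the flat-detector acceptance")
  r_max_px <- geometry@distance_mm * tan(tt_max * pi / 180) / px_mm
  if (is.null(dim)) {
    n <- 2L * ceiling(r_max_px) + 1L
    dim <- c(n, n)
  }
  ny <- dim[1]; nx <- dim[2]
  bc <- geometry@beam_center_px
  if (any(is.na(bc))) bc <- c((nx + 1) / 2, (ny + 1) / 2)
  # corner acceptance check: pattern must fit on the frame
  corner_r <- max(sqrt(outer((c(1, ny) - bc[2])^2, (c(1, nx) - bc[1])^2, "+")))
  if (r_max_px > corner_r)
    stop("pattern range exceeds the detector acceptance for this frame size")
  xs <- seq_len(nx); ys <- seq_len(ny)
  r_px <- sqrt(outer((ys - bc[2])^2, (xs - bc[1])^2, "+"))
  tt <- atan(r_px * px_mm / geometry@distance_mm) * 180 / pi
  fint <- splinefun(twoTheta(pattern), intensityValues(pattern),
                    method = "monoH.FC")
  frame <- matrix(fint(pmin(pmax(tt, min(twoTheta(pattern))), tt_max)), ny, nx)
  if (noise_sd > 0) frame <- frame + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
  mask <- matrix(FALSE, ny, nx)
  if (!is.null(slit_rows))
    mask[slit_rows[1]:slit_rows[2], ] <- TRUE
  geometry@beam_center_px <- bc
  list(frame = frame, mask = mask, geometry = geometry)
}

#' Reference cellulose I-beta reflection positions
#'
#' Nominal 2-theta positions (Cu K-alpha, 1.54 Angstrom) and Miller labels of
#' the main cellulose I-beta reflections, shipped as a small packaged table
#' and used as default initial centers for \code{\link{fitPeaks}}.
#'
#' @return data.frame with columns \code{label} and \code{twotheta_deg}.
#' @examples
#' celluloseIbetaPeaks()
#' @export
celluloseIbetaPeaks <- function() {
  read.csv(system.file("extdata", "cellulose_ibeta_reference.csv",
                       package = "pellimetrics"), stringsAsFactors = FALSE)
}
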