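# Reduction of 2D WAXS detector frames to 1D diffractograms.

#' Merge two shifted detector frames to erase a slit
#'
#' Combines two exposures of the same pattern taken with a slightly shifted
#' detector so that the module slit of one frame is covered by valid pixels of
#' the other: the output is the per-pixel mean of the unmasked contributions.
#' Pixels masked in both frames are returned as \code{NA} and carry a
#' \code{TRUE} in the returned mask so that downstream integration excludes
#' them.
#'
#' @param frame_a,frame_b numeric matrices of equal size.
#' @param mask_a,mask_b logical matrices (TRUE = masked); defaults all-FALSE.
#' @return A list with \code{frame} (merged matrix, NA where invalid) and
#'   \code{mask} (logical, TRUE = invalid).
#' @export
mergeLineEraser <- function(frame_a, frame_b, mask_a = NULL, mask_b = NULL) {
  if (!all(dim(frame_a) == dim(frame_b)))
    stop("frames have incompatible shapes")
  if (is.null(mask_a)) mask_a <- matrix(FALSE, nrow(frame_a), ncol(frame_a))
  if (is.null(mask_b)) mask_b <- matrix(FALSE, nrow(frame_b), ncol(frame_b))
  wa <- !mask_a; wb <- !mask_b
  num <- ifelse(wa, frame_a, 0) + ifelse(wb, frame_b, 0)
  den <- wa + wb
  out <- ifelse(den > 0, num / pmax(den, 1L), NA_real_)
  list(frame = out, mask = den == 0)
}

#' Azimuthally integrate a detector frame
#'
#' Computes the scattering angle of every pixel on a flat, normally incident
#' detector (2-theta = atan(r / distance)) and averages pixel intensities into
#' equal-width 2-theta bins. Masked or non-finite pixels are excluded; bins
#' that receive no pixels are returned as \code{NA}.
#'
#' @param frame numeric matrix (may contain NA for invalid pixels).
#' @param geometry a \code{\link{detectorGeometry}}; a beam center of NA means
#'   the frame center.
#' @param n_bins number of 2-theta bins (>= 50).
#' @param mask optional logical matrix, TRUE = exclude.
#' @param range_deg optional c(min, max) 2-theta range; defaults to the range
#'   present on the frame.
#' @return A \code{\link{diffractogram1D}} on the bin centers.
#' @export
integrateAzimuthal <- function(frame, geometry = detectorGeometry(),
                               n_bins = 400, mask = NULL, range_deg = NULL) {
  stopifnot(is(geometry, "DetectorGeometry"))
  if (n_bins < 50) stop("n_bins must be >= 50")
  ny <- nrow(frame); nx <- ncol(frame)
  if (is.null(mask)) {
    mask <- if (length(geometry@mask) && all(dim(geometry@mask) == dim(frame)))
      geometry@mask else matrix(FALSE, ny, nx)
  }
  bc <- geometry@beam_center_px
  if (any(is.na(bc))) bc <- c((nx + 1) / 2, (ny + 1) / 2)
  px_mm <- geometry@pixel_size_um / 1000
  r_px <- sqrt(outer((seq_len(ny) - bc[2])^2, (seq_len(nx) - bc[1])^2, "+"))
  tt <- atan(r_px * px_mm / geometry@distance_mm) * 180 / pi
  keep <- !mask & is.finite(frame)
  if (!any(keep)) stop("all pixels are masked or invalid")
  if (is.null(range_deg)) range_deg <- range(tt[keep])
  edges <- seq(range_deg[1], range_deg[2], length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- findInterval(tt[keep], edges, rightmost.closed = TRUE)
  inb <- bin >= 1 & bin <= n_bins
  v <- frame[keep][inb]
  b <- bin[inb]
  sums <- rowsum(v, b)
  cnts <- rowsum(rep(1, length(b)), b)
  intensity <- rep(NA_real_, n_bins)
  intensity[as.integer(rownames(sums))] <- sums / cnts
  diffractogram1D(centers, intensity, geometry@wavelength_A)
}

#' Convert scattering angle to scattering vector
#'
#' q = 4 pi sin(theta) / lambda with theta = 2-theta / 2.
#'
#' @param twotheta_deg scattering angle(s) in degrees.
#' @param wavelength_A wavelength in Angstrom.
#' @return q in inverse Angstrom.
#' @examples
#' twoThetaToQ(22.7, 1.54)
#' @export
twoThetaToQ <- function(twotheta_deg, wavelength_A = 1.54) {
  4 * pi * sin(twotheta_deg / 2 * pi / 180) / wavelength_A
}
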