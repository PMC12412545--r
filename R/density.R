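# Equivalent-cylinder wet-pellicle density from a side-view photograph and
# the dry mass.

#' Segment the pellicle cross-section from a side-view photograph
#'
#' Thresholds the grayscale photograph with Otsu's global method, keeps the
#' largest connected foreground component and converts its pixel count to an
#' area via the mm-per-pixel scale.
#'
#' @param photo numeric matrix, grayscale side view (foreground bright).
#' @param scale_mm_per_px physical size of one pixel in mm.
#' @param threshold optional manual threshold overriding Otsu.
#' @return A list with \code{area_mm2}, \code{threshold} and \code{mask}
#'   (logical matrix of the retained component).
#' @export
segmentCrossSection <- function(photo, scale_mm_per_px, threshold = NULL) {
  stopifnot(scale_mm_per_px > 0)
  rng <- range(photo)
  if (diff(rng) == 0) stop("photograph has no contrast")
  norm <- (photo - rng[1]) / diff(rng)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  } else {
    threshold <- (threshold - rng[1]) / diff(rng)
  }
  fg <- norm > threshold
  if (!any(fg)) stop("empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  tab <- tabulate(as.integer(lab))
  keep <- which.max(tab)
  mask <- matrix(as.integer(lab) == keep, nrow(photo), ncol(photo))
  list(area_mm2 = sum(mask) * scale_mm_per_px^2,
       threshold = threshold * diff(rng) + rng[1], mask = mask)
}

#' Pellicle density from the equivalent-cylinder model
#'
#' Equates the segmented side-view area A to the cross-section of a cylinder
#' with the container radius r: h = A / (2 r), V = pi r^2 h, and
#' rho = W / V from the dry mass W, reported in mg per cubic centimeter.
#'
#' @param area_mm2 segmented cross-section area (mm^2).
#' @param container_radius_mm radius r of the culture container (mm).
#' @param dry_mass_mg dry pellicle mass W (mg).
#' @return A \code{PellicleGeometry}.
#' @examples
#' pellicleDensity(200, 20, 31.416)
#' @export
pellicleDensity <- function(area_mm2, container_radius_mm, dry_mass_mg) {
  if (any(c(area_mm2, container_radius_mm, dry_mass_mg) <= 0))
    stop("all inputs must be > 0")
  h <- area_mm2 / (2 * container_radius_mm)
  V <- pi * container_radius_mm^2 * h
  rho <- dry_mass_mg / (V / 1000)  # mm^3 -> cm^3
  new("PellicleGeometry", area_measured_mm2 = area_mm2,
      container_radius_mm = container_radius_mm, equiv_height_mm = h,
      volume_mm3 = V, dry_mass_mg = dry_mass_mg, density_mg_cm3 = rho)
}
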