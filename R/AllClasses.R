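# ---- synthetic-data ground truth ------------------------------------------

#' Ground truth for a synthetic blinking-fluorophore fiber
#'
#' Describes a single cellulose fiber as alternating crystalline (dark, the
#' dye binds poorly) and amorphous (bright, preferentially stained) domains
#' laid out along a polyline in pixel coordinates, plus the imaging model
#' parameters used by \code{\link{genFiberStack}}.
#'
#' @slot states character vector, each \code{"crystalline"} or
#'   \code{"amorphous"}, alternating along the fiber.
#' @slot lengths_nm positive domain lengths, one per state.
#' @slot path_px two-column matrix (x, y) of polyline vertices in pixel
#'   coordinates (1-based pixel centers); may have zero rows, in which case
#'   generators lay the fiber out horizontally with an adequate margin.
#' @slot pixel_size_nm physical size of one camera pixel (nm).
#' @slot emitter_density_um mean number of fluorophores per micrometer of
#'   amorphous fiber length.
#' @slot blink_prob per-frame probability that an emitter is on.
#' @slot psf_sigma_px Gaussian PSF standard deviation in pixels.
#' @slot contrast_ratio staining contrast amorphous:crystalline; \code{Inf}
#'   (the default) means crystalline domains carry no emitters at all.
#' @slot peak_intensity expected photon count at the center of one emitter.
#' @slot background mean background photon count per pixel per frame.
#' @slot true_crystallinity fraction of total length in crystalline domains.
#' @export
setClass("GroundTruthFiber", representation(
  states = "character", lengths_nm = "numeric", path_px = "matrix",
  pixel_size_nm = "numeric", emitter_density_um = "numeric",
  blink_prob = "numeric", psf_sigma_px = "numeric", contrast_ratio = "numeric",
  peak_intensity = "numeric", background = "numeric",
  true_crystallinity = "numeric"))

setValidity("GroundTruthFiber", function(object) {
  msg <- character()
  if (length(object@states) != length(object@lengths_nm))
    msg <- c(msg, "states and lengths_nm differ in length")
  if (!all(object@states %in% c("crystalline", "amorphous")))
    msg <- c(msg, "states must be 'crystalline' or 'amorphous'")
  if (any(object@lengths_nm <= 0)) msg <- c(msg, "all domain lengths must be > 0")
  if (object@pixel_size_nm <= 0) msg <- c(msg, "pixel_size_nm must be > 0")
  if (object@blink_prob < 0 || object@blink_prob > 1)
    msg <- c(msg, "blink_prob must lie in [0, 1]")
  cr <- sum(object@lengths_nm[object@states == "crystalline"]) /
    sum(object@lengths_nm)
  if (abs(cr - object@true_crystallinity) > 1e-12)
    msg <- c(msg, "true_crystallinity inconsistent with domain lengths")
  if (length(msg)) msg else TRUE
})

#' Construct a fiber ground truth
#'
#' @param states alternating \code{"crystalline"}/\code{"amorphous"} labels.
#' @param lengths_nm matching positive lengths in nm.
#' @param path_px optional polyline (x, y) in pixels; autogenerated if omitted.
#' @param pixel_size_nm nm per pixel (default 65, a 100x TIRF setup).
#' @param emitter_density_um emitters per micrometer in amorphous domains.
#'   The default (250, one binding site every ~4 nm) emulates the dense
#'   quasi-continuous staining of a cellulose-binding dye.
#' @param blink_prob per-frame on-probability of an emitter. The default 0.2
#'   keeps simultaneously active emitters sparse enough for radial-fluctuation
#'   analysis while giving ample temporal co-activation statistics.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param contrast_ratio amorphous:crystalline staining contrast
#'   (\code{Inf}: crystalline strictly dark).
#' @param peak_intensity photons at an emitter center when on.
#' @param background mean background photons per pixel.
#' @return A \code{GroundTruthFiber}.
#' @examples
#' ft <- fiberTruth(rep(c("crystalline", "amorphous"), 5),
#'                  rep(c(600, 200), 5))
#' trueCrystallinity(ft)
#' @export
fiberTruth <- function(states, lengths_nm, path_px = NULL,
                       pixel_size_nm = 65, emitter_density_um = 250,
                       blink_prob = 0.2, psf_sigma_px = 1.0,
                       contrast_ratio = Inf, peak_intensity = 150,
                       background = 10) {
  if (is.null(path_px)) path_px <- matrix(numeric(0), 0, 2)
  new("GroundTruthFiber", states = states, lengths_nm = as.numeric(lengths_nm),
      path_px = path_px, pixel_size_nm = pixel_size_nm,
      emitter_density_um = emitter_density_um, blink_prob = blink_prob,
      psf_sigma_px = psf_sigma_px, contrast_ratio = contrast_ratio,
      peak_intensity = peak_intensity, background = background,
      true_crystallinity = sum(lengths_nm[states == "crystalline"]) /
        sum(lengths_nm))
}

#' Draw a random fiber ground truth with realistic domain lengths
#'
#' Domain lengths are drawn uniformly from the ranges typical of bacterial
#' cellulose fibers: crystalline domains of 510-600 nm and amorphous domains
#' of 167-192 nm, which puts the crystallinity near 75\%.
#'
#' @param n_pairs number of crystalline/amorphous domain pairs.
#' @param crystalline_nm,amorphous_nm length ranges (nm) to draw from.
#' @param seed integer seed (generator is fully deterministic given it).
#' @param ... further arguments to \code{\link{fiberTruth}}.
#' @return A \code{GroundTruthFiber}.
#' @export
randomFiberTruth <- function(n_pairs = 5, crystalline_nm = c(510, 600),
                             amorphous_nm = c(167, 192), seed = 1, ...) {
  set.seed(seed)
  cl <- runif(n_pairs, crystalline_nm[1], crystalline_nm[2])
  al <- runif(n_pairs, amorphous_nm[1], amorphous_nm[2])
  states <- rep(c("crystalline", "amorphous"), n_pairs)
  lengths <- as.numeric(rbind(cl, al))
  fiberTruth(states, lengths, ...)
}

#' Ground truth for a synthetic WAXS pattern
#'
#' A 1D diffraction pattern described as crystalline pseudo-Voigt peaks on a
#' broad amorphous halo; the area-based crystalline fraction over the
#' standard 10-45 degree window is stored alongside.
#'
#' @slot peaks matrix with columns \code{center_deg}, \code{fwhm_deg},
#'   \code{area}, \code{eta} (one row per crystalline reflection).
#' @slot halo matrix with columns \code{center_deg}, \code{sigma_deg},
#'   \code{amplitude} describing Gaussian halo components.
#' @slot noise_sd Gaussian noise standard deviation (counts).
#' @slot crystalline_fraction area fraction of the peaks over [10, 45] deg.
#' @export
setClass("GroundTruthPattern", representation(
  peaks = "matrix", halo = "matrix", noise_sd = "numeric",
  crystalline_fraction = "numeric"))

setValidity("GroundTruthPattern", function(object) {
  msg <- character()
  f <- object@crystalline_fraction
  if (f < 0 || f > 1) msg <- c(msg, "crystalline_fraction must lie in [0, 1]")
  if (nrow(object@peaks) > 0) {
    if (any(object@peaks[, "fwhm_deg"] <= 0)) msg <- c(msg, "peak FWHM must be > 0")
    ctr <- object@peaks[, "center_deg"]
    if (any(ctr <= 10 | ctr >= 45))
      msg <- c(msg, "peak centers must lie inside (10, 45) degrees")
  }
  if (length(msg)) msg else TRUE
})

# ---- imaging / SRRF --------------------------------------------------------

#' SRRF reconstruction parameters
#'
#' Defaults follow common practice for single-fiber TIRF reconstructions:
#' ring radius 0.5 px, radiality magnification 10, 8 axes in the ring,
#' temporal combination by auto-correlation (TRAC, order 2) and image-based
#' drift correction.
#'
#' @slot ring_radius_px radius of the gradient-sampling ring, in pixels.
#' @slot magnification integer radiality magnification.
#' @slot axes integer number of ring axes (even, at least 4).
#' @slot trac_lag temporal lag of the order-2 auto-correlation (1 = pairwise
#'   consecutive products, 0 = mean-square variant).
#' @slot drift_correction logical, register frames before reconstruction.
#' @slot intensity_weighting logical, weight radiality by the interpolated
#'   image intensity.
#' @export
setClass("SRRFParams", representation(
  ring_radius_px = "numeric", magnification = "integer", axes = "integer",
  trac_lag = "integer", drift_correction = "logical",
  intensity_weighting = "logical"))

setValidity("SRRFParams", function(object) {
  msg <- character()
  if (object@ring_radius_px <= 0) msg <- c(msg, "ring_radius_px must be > 0")
  if (object@magnification < 1L) msg <- c(msg, "magnification must be >= 1")
  if (object@axes < 4L || object@axes %% 2L != 0L)
    msg <- c(msg, "axes must be even and >= 4")
  if (!object@trac_lag %in% c(0L, 1L)) msg <- c(msg, "trac_lag must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' @param ring_radius_px,magnification,axes,trac_lag,drift_correction,intensity_weighting
#'   see the class slots.
#' @return An \code{SRRFParams} object.
#' @rdname SRRFParams-class
#' @examples
#' srrfParams(magnification = 5)
#' @export
srrfParams <- function(ring_radius_px = 0.5, magnification = 10L, axes = 8L,
                       trac_lag = 1L, drift_correction = TRUE,
                       intensity_weighting = TRUE) {
  new("SRRFParams", ring_radius_px = ring_radius_px,
      magnification = as.integer(magnification), axes = as.integer(axes),
      trac_lag = as.integer(trac_lag), drift_correction = drift_correction,
      intensity_weighting = intensity_weighting)
}

# ---- fiber domain analysis -------------------------------------------------

#' Intensity profile along a traced fiber
#'
#' @slot positions_nm strictly increasing arclength positions (nm).
#' @slot intensities matched intensity values.
#' @slot pixel_size_nm nm per pixel of the image the profile was read from.
#' @slot averaging_width_nm transverse averaging width (nm).
#' @export
setClass("IntensityProfile", representation(
  positions_nm = "numeric", intensities = "numeric",
  pixel_size_nm = "numeric", averaging_width_nm = "numeric"))

setValidity("IntensityProfile", function(object) {
  msg <- character()
  if (length(object@positions_nm) != length(object@intensities))
    msg <- c(msg, "positions and intensities differ in length")
  if (any(diff(object@positions_nm) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (object@averaging_width_nm <= 0)
    msg <- c(msg, "averaging_width_nm must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param positions_nm,intensities,pixel_size_nm,averaging_width_nm see slots.
#' @return An \code{IntensityProfile}.
#' @rdname IntensityProfile-class
#' @export
intensityProfile <- function(positions_nm, intensities, pixel_size_nm = NA_real_,
                             averaging_width_nm = 3000) {
  new("IntensityProfile", positions_nm = as.numeric(positions_nm),
      intensities = as.numeric(intensities), pixel_size_nm = pixel_size_nm,
      averaging_width_nm = averaging_width_nm)
}

#' Filtered peak set of a fiber intensity profile
#'
#' Peaks retained by the three filters applied to amorphous-domain peaks:
#' minimum FWHM, minimum spacing and the per-fiber median-prominence cut.
#'
#' @slot peaks data.frame with columns \code{position_nm}, \code{height},
#'   \code{prominence}, \code{fwhm_nm}, \code{left_half_nm},
#'   \code{right_half_nm}.
#' @slot median_prominence the per-fiber median prominence used as threshold.
#' @slot min_fwhm_nm,min_spacing_nm the applied filter floors.
#' @export
setClass("PeakSet", representation(
  peaks = "data.frame", median_prominence = "numeric",
  min_fwhm_nm = "numeric", min_spacing_nm = "numeric"))

#' Crystalline/amorphous domain segmentation of one fiber
#'
#' Bright (amorphous) lengths are the retained peak FWHMs; dark (crystalline)
#' lengths are the distances between adjacent peaks at half maximum. The
#' crystallinity is the percentage of total length in dark domains.
#'
#' @slot bright_lengths_nm amorphous domain lengths (nm).
#' @slot dark_lengths_nm crystalline domain lengths (nm).
#' @slot crystallinity_pct 100 * sum(dark) / (sum(dark) + sum(bright)).
#' @export
setClass("DomainSegmentation", representation(
  bright_lengths_nm = "numeric", dark_lengths_nm = "numeric",
  crystallinity_pct = "numeric"))

setValidity("DomainSegmentation", function(object) {
  msg <- character()
  if (any(c(object@bright_lengths_nm, object@dark_lengths_nm) <= 0))
    msg <- c(msg, "all domain lengths must be > 0")
  if (abs(length(object@dark_lengths_nm) - length(object@bright_lengths_nm)) > 1)
    msg <- c(msg, "dark and bright domain counts must differ by at most 1")
  expect <- 100 * sum(object@dark_lengths_nm) /
    (sum(object@dark_lengths_nm) + sum(object@bright_lengths_nm))
  if (abs(expect - object@crystallinity_pct) > 1e-9)
    msg <- c(msg, "crystallinity_pct inconsistent with domain lengths")
  if (object@crystallinity_pct < 0 || object@crystallinity_pct > 100)
    msg <- c(msg, "crystallinity_pct must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

# ---- WAXS ------------------------------------------------------------------

#' Flat-detector WAXS geometry
#'
#' @slot wavelength_A X-ray wavelength in Angstrom (default Cu K-alpha, 1.54).
#' @slot distance_mm sample-detector distance (default 50).
#' @slot pixel_size_um detector pixel pitch (default 75).
#' @slot beam_center_px beam center (x, y) in pixels; \code{NA} = frame center.
#' @slot mask logical matrix of masked pixels (TRUE = masked), possibly empty.
#' @export
setClass("DetectorGeometry", representation(
  wavelength_A = "numeric", distance_mm = "numeric", pixel_size_um = "numeric",
  beam_center_px = "numeric", mask = "matrix"))

setValidity("DetectorGeometry", function(object) {
  msg <- character()
  if (object@wavelength_A <= 0) msg <- c(msg, "wavelength_A must be > 0")
  if (object@distance_mm <= 0) msg <- c(msg, "distance_mm must be > 0")
  if (object@pixel_size_um <= 0) msg <- c(msg, "pixel_size_um must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param wavelength_A,distance_mm,pixel_size_um,beam_center_px,mask see slots.
#' @return A \code{DetectorGeometry}.
#' @rdname DetectorGeometry-class
#' @examples
#' detectorGeometry()
#' @export
detectorGeometry <- function(wavelength_A = 1.54, distance_mm = 50,
                             pixel_size_um = 75,
                             beam_center_px = c(NA_real_, NA_real_),
                             mask = matrix(logical(0), 0, 0)) {
  new("DetectorGeometry", wavelength_A = wavelength_A,
      distance_mm = distance_mm, pixel_size_um = pixel_size_um,
      beam_center_px = as.numeric(beam_center_px), mask = mask)
}

#' One-dimensional diffractogram
#'
#' @slot twotheta_deg strictly increasing scattering-angle grid (degrees).
#' @slot intensity counts on that grid.
#' @slot q_invA scattering vector q = 4 pi sin(theta) / lambda (1/Angstrom).
#' @slot wavelength_A wavelength used for the q conversion.
#' @export
setClass("Diffractogram1D", representation(
  twotheta_deg = "numeric", intensity = "numeric", q_invA = "numeric",
  wavelength_A = "numeric"))

setValidity("Diffractogram1D", function(object) {
  msg <- character()
  if (any(diff(object@twotheta_deg) <= 0))
    msg <- c(msg, "twotheta_deg must be strictly increasing")
  if (length(object@twotheta_deg) != length(object@intensity))
    msg <- c(msg, "grid and intensity differ in length")
  qexp <- twoThetaToQ(object@twotheta_deg, object@wavelength_A)
  if (max(abs(qexp - object@q_invA)) > 1e-9)
    msg <- c(msg, "q_invA inconsistent with twotheta_deg and wavelength")
  if (length(msg)) msg else TRUE
})

#' @param twotheta_deg,intensity,wavelength_A see slots; q is derived.
#' @return A \code{Diffractogram1D}.
#' @rdname Diffractogram1D-class
#' @export
diffractogram1D <- function(twotheta_deg, intensity, wavelength_A = 1.54) {
  new("Diffractogram1D", twotheta_deg = as.numeric(twotheta_deg),
      intensity = as.numeric(intensity),
      q_invA = twoThetaToQ(as.numeric(twotheta_deg), wavelength_A),
      wavelength_A = wavelength_A)
}

#' Fitted amorphous background of a diffractogram
#'
#' @slot model background model used (\code{"anchor_spline"} or
#'   \code{"broad_halo"}).
#' @slot anchors_deg 2-theta positions of the anchor points.
#' @slot background intensity of the background curve on the full grid.
#' @slot range_deg the integration range.
#' @slot area_background trapezoidal area of the background over the range.
#' @export
setClass("BackgroundFit", representation(
  model = "character", anchors_deg = "numeric", background = "numeric",
  range_deg = "numeric", area_background = "numeric"))

#' Fitted crystalline peaks of a diffractogram
#'
#' @slot peaks data.frame with columns \code{center_deg}, \code{fwhm_deg},
#'   \code{height}, \code{eta} and optionally \code{label}.
#' @slot baseline intercept and slope of the local linear residual-background
#'   term co-fitted with the peaks (zeros when disabled).
#' @slot converged logical convergence flag of the nonlinear fit.
#' @slot message optimizer diagnostics.
#' @export
setClass("PeakFit", representation(
  peaks = "data.frame", baseline = "numeric", converged = "logical",
  message = "character"))

#' WAXS crystallinity, lattice-spacing and crystallite-size result
#'
#' @slot area_sample trapezoidal area of the measured intensity over the range.
#' @slot area_background area of the fitted amorphous background.
#' @slot crystallinity_pct 100 * (area_sample - area_background) / area_sample,
#'   clamped to [0, 100].
#' @slot range_deg the 2-theta integration range.
#' @slot peaks data.frame of fitted peaks with Bragg spacings (Angstrom) and
#'   Scherrer sizes (nm) appended.
#' @export
setClass("CrystallinityResult", representation(
  area_sample = "numeric", area_background = "numeric",
  crystallinity_pct = "numeric", range_deg = "numeric", peaks = "data.frame"))

setValidity("CrystallinityResult", function(object) {
  raw <- 100 * (object@area_sample - object@area_background) / object@area_sample
  if (abs(min(max(raw, 0), 100) - object@crystallinity_pct) > 1e-9)
    return("crystallinity_pct inconsistent with stored areas")
  TRUE
})

# ---- Raman -----------------------------------------------------------------

#' Raman spectrum with a processing log
#'
#' @slot wavenumber_cm1 strictly increasing Raman shift grid (1/cm).
#' @slot counts intensities.
#' @slot processing_log ordered record of the applied processing steps.
#' @export
setClass("RamanSpectrum", representation(
  wavenumber_cm1 = "numeric", counts = "numeric", processing_log = "character"))

setValidity("RamanSpectrum", function(object) {
  msg <- character()
  if (any(diff(object@wavenumber_cm1) <= 0))
    msg <- c(msg, "wavenumber grid must be strictly increasing")
  if (length(object@wavenumber_cm1) != length(object@counts))
    msg <- c(msg, "grid and counts differ in length")
  if (length(msg)) msg else TRUE
})

#' @param wavenumber_cm1,counts see slots.
#' @return A \code{RamanSpectrum} with an empty processing log.
#' @rdname RamanSpectrum-class
#' @export
ramanSpectrum <- function(wavenumber_cm1, counts) {
  new("RamanSpectrum", wavenumber_cm1 = as.numeric(wavenumber_cm1),
      counts = as.numeric(counts), processing_log = character())
}

# ---- mechanics -------------------------------------------------------------

#' Dogbone tensile-specimen geometry
#'
#' @slot width_mm gauge width (default 2 mm).
#' @slot gauge_length_mm starting grip spacing taken as gauge length
#'   (default 20 mm).
#' @slot thickness_mm measured specimen thickness.
#' @export
setClass("DogboneGeometry", representation(
  width_mm = "numeric", gauge_length_mm = "numeric", thickness_mm = "numeric"))

setValidity("DogboneGeometry", function(object) {
  if (any(c(object@width_mm, object@gauge_length_mm, object@thickness_mm) <= 0))
    return("all dogbone dimensions must be > 0")
  TRUE
})

#' @param width_mm,gauge_length_mm,thickness_mm see slots.
#' @return A \code{DogboneGeometry}.
#' @rdname DogboneGeometry-class
#' @examples
#' dogboneGeometry(thickness_mm = 0.5)
#' @export
dogboneGeometry <- function(width_mm = 2, gauge_length_mm = 20,
                            thickness_mm = 0.5) {
  new("DogboneGeometry", width_mm = width_mm,
      gauge_length_mm = gauge_length_mm, thickness_mm = thickness_mm)
}

#' Engineering stress-strain curve
#'
#' @slot strain engineering strain (dimensionless), non-decreasing.
#' @slot stress_MPa engineering stress.
#' @slot onset_shift_applied logical, was the minimum-onset crop applied.
#' @slot geometry the \code{DogboneGeometry} used for the conversion.
#' @export
setClass("TensileCurve", representation(
  strain = "numeric", stress_MPa = "numeric", onset_shift_applied = "logical",
  geometry = "DogboneGeometry"))

setValidity("TensileCurve", function(object) {
  msg <- character()
  if (length(object@strain) != length(object@stress_MPa))
    msg <- c(msg, "strain and stress differ in length")
  if (any(diff(object@strain) < -1e-12))
    msg <- c(msg, "strain must be non-decreasing")
  if (!all(is.finite(object@stress_MPa))) msg <- c(msg, "stress must be finite")
  if (length(msg)) msg else TRUE
})

# ---- density ---------------------------------------------------------------

#' Equivalent-cylinder pellicle geometry and density
#'
#' The wet pellicle is modelled as a cylinder with the container radius r;
#' its side-view cross-section area A gives the equivalent height
#' h = A / (2 r), the volume V = pi r^2 h, and the density rho = W / V from
#' the dry mass W.
#'
#' @slot area_measured_mm2 segmented side-view cross-section area.
#' @slot container_radius_mm radius of the culture container.
#' @slot equiv_height_mm equivalent cylinder height.
#' @slot volume_mm3 equivalent cylinder volume.
#' @slot dry_mass_mg dry mass of the pellicle.
#' @slot density_mg_cm3 derived density in mg per cubic centimeter.
#' @export
setClass("PellicleGeometry", representation(
  area_measured_mm2 = "numeric", container_radius_mm = "numeric",
  equiv_height_mm = "numeric", volume_mm3 = "numeric", dry_mass_mg = "numeric",
  density_mg_cm3 = "numeric"))

setValidity("PellicleGeometry", function(object) {
  msg <- character()
  h <- object@area_measured_mm2 / (2 * object@container_radius_mm)
  V <- pi * object@container_radius_mm^2 * h
  rho <- object@dry_mass_mg / (V / 1000)
  if (abs(h - object@equiv_height_mm) > 1e-9 * max(1, h))
    msg <- c(msg, "equiv_height_mm inconsistent")
  if (abs(V - object@volume_mm3) > 1e-9 * max(1, V))
    msg <- c(msg, "volume_mm3 inconsistent")
  if (abs(rho - object@density_mg_cm3) > 1e-9 * max(1, rho))
    msg <- c(msg, "density_mg_cm3 inconsistent")
  if (any(c(h, V, rho) <= 0)) msg <- c(msg, "geometry must be positive")
  if (length(msg)) msg else TRUE
})
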