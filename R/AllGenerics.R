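# Accessor generics and show methods. Slots are never reached into directly
# by user code; these accessors are the supported surface.

#' True crystalline fraction stored in a ground-truth object
#' @param object a ground-truth object.
#' @return Numeric fraction in [0, 1].
#' @export
setGeneric("trueCrystallinity", function(object) standardGeneric("trueCrystallinity"))

#' @rdname trueCrystallinity
#' @export
setMethod("trueCrystallinity", "GroundTruthFiber",
          function(object) object@true_crystallinity)

#' @rdname trueCrystallinity
#' @export
setMethod("trueCrystallinity", "GroundTruthPattern",
          function(object) object@crystalline_fraction)

#' Arclength positions of an intensity profile (nm)
#' @param object an \code{IntensityProfile}.
#' @return Numeric vector.
#' @export
setGeneric("profilePositions", function(object) standardGeneric("profilePositions"))

#' @rdname profilePositions
#' @export
setMethod("profilePositions", "IntensityProfile",
          function(object) object@positions_nm)

#' Intensity values of an intensity profile
#' @param object an \code{IntensityProfile}.
#' @return Numeric vector.
#' @export
setGeneric("profileIntensities", function(object) standardGeneric("profileIntensities"))

#' @rdname profileIntensities
#' @export
setMethod("profileIntensities", "IntensityProfile",
          function(object) object@intensities)

#' Table of retained or fitted peaks
#' @param object a \code{PeakSet} or \code{PeakFit}.
#' @return A data.frame, one row per peak.
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' @rdname peakTable
#' @export
setMethod("peakTable", "PeakSet", function(object) object@peaks)

#' @rdname peakTable
#' @export
setMethod("peakTable", "PeakFit", function(object) object@peaks)

#' @rdname peakTable
#' @export
setMethod("peakTable", "CrystallinityResult", function(object) object@peaks)

#' Amorphous (bright) domain lengths in nm
#' @param object a \code{DomainSegmentation}.
#' @return Numeric vector.
#' @export
setGeneric("brightLengths", function(object) standardGeneric("brightLengths"))

#' @rdname brightLengths
#' @export
setMethod("brightLengths", "DomainSegmentation",
          function(object) object@bright_lengths_nm)

#' Crystalline (dark) domain lengths in nm
#' @param object a \code{DomainSegmentation}.
#' @return Numeric vector.
#' @export
setGeneric("darkLengths", function(object) standardGeneric("darkLengths"))

#' @rdname darkLengths
#' @export
setMethod("darkLengths", "DomainSegmentation",
          function(object) object@dark_lengths_nm)

#' Crystallinity percentage of an analysis result
#' @param object a \code{DomainSegmentation} or \code{CrystallinityResult}.
#' @return Numeric scalar in [0, 100].
#' @export
setGeneric("crystallinity", function(object) standardGeneric("crystallinity"))

#' @rdname crystallinity
#' @export
setMethod("crystallinity", "DomainSegmentation",
          function(object) object@crystallinity_pct)

#' @rdname crystallinity
#' @export
setMethod("crystallinity", "CrystallinityResult",
          function(object) object@crystallinity_pct)

#' Scattering-angle grid of a diffractogram (degrees 2-theta)
#' @param object a \code{Diffractogram1D}.
#' @return Numeric vector.
#' @export
setGeneric("twoTheta", function(object) standardGeneric("twoTheta"))

#' @rdname twoTheta
#' @export
setMethod("twoTheta", "Diffractogram1D", function(object) object@twotheta_deg)

#' Intensity of a diffractogram or spectrum
#' @param object a \code{Diffractogram1D} or \code{RamanSpectrum}.
#' @return Numeric vector.
#' @export
setGeneric("intensityValues", function(object) standardGeneric("intensityValues"))

#' @rdname intensityValues
#' @export
setMethod("intensityValues", "Diffractogram1D", function(object) object@intensity)

#' @rdname intensityValues
#' @export
setMethod("intensityValues", "RamanSpectrum", function(object) object@counts)

#' Scattering vector q of a diffractogram (1/Angstrom)
#' @param object a \code{Diffractogram1D}.
#' @return Numeric vector.
#' @export
setGeneric("scatteringQ", function(object) standardGeneric("scatteringQ"))

#' @rdname scatteringQ
#' @export
setMethod("scatteringQ", "Diffractogram1D", function(object) object@q_invA)

#' Background curve of a background fit
#' @param object a \code{BackgroundFit}.
#' @return Numeric vector on the diffractogram grid.
#' @export
setGeneric("backgroundCurve", function(object) standardGeneric("backgroundCurve"))

#' @rdname backgroundCurve
#' @export
setMethod("backgroundCurve", "BackgroundFit", function(object) object@background)

#' Wavenumber grid of a Raman spectrum (1/cm)
#' @param object a \code{RamanSpectrum}.
#' @return Numeric vector.
#' @export
setGeneric("wavenumbers", function(object) standardGeneric("wavenumbers"))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "RamanSpectrum", function(object) object@wavenumber_cm1)

#' Processing log of a Raman spectrum
#' @param object a \code{RamanSpectrum}.
#' @return Character vector of applied steps, in order.
#' @export
setGeneric("processingLog", function(object) standardGeneric("processingLog"))

#' @rdname processingLog
#' @export
setMethod("processingLog", "RamanSpectrum", function(object) object@processing_log)

#' Strain values of a tensile curve
#' @param object a \code{TensileCurve}.
#' @return Numeric vector (engineering strain).
#' @export
setGeneric("curveStrain", function(object) standardGeneric("curveStrain"))

#' @rdname curveStrain
#' @export
setMethod("curveStrain", "TensileCurve", function(object) object@strain)

#' Stress values of a tensile curve (MPa)
#' @param object a \code{TensileCurve}.
#' @return Numeric vector.
#' @export
setGeneric("curveStress", function(object) standardGeneric("curveStress"))

#' @rdname curveStress
#' @export
setMethod("curveStress", "TensileCurve", function(object) object@stress_MPa)

#' Density of a pellicle (mg per cubic centimeter)
#' @param object a \code{PellicleGeometry}.
#' @return Numeric scalar.
#' @export
setGeneric("pellicleDensityValue", function(object) standardGeneric("pellicleDensityValue"))

#' @rdname pellicleDensityValue
#' @export
setMethod("pellicleDensityValue", "PellicleGeometry",
          function(object) object@density_mg_cm3)

# ---- show methods ----------------------------------------------------------

setMethod("show", "GroundTruthFiber", function(object) {
  cat(sprintf("GroundTruthFiber: %d domains, total %.0f nm, crystallinity %.1f%%\n",
              length(object@states), sum(object@lengths_nm),
              100 * object@true_crystallinity))
})

setMethod("show", "GroundTruthPattern", function(object) {
  cat(sprintf("GroundTruthPattern: %d peaks, crystalline fraction %.3f\n",
              nrow(object@peaks), object@crystalline_fraction))
})

setMethod("show", "IntensityProfile", function(object) {
  n <- length(object@positions_nm)
  cat(sprintf("IntensityProfile: %d samples over %.0f nm (width %.0f nm)\n",
              n, if (n) diff(range(object@positions_nm)) else 0,
              object@averaging_width_nm))
})

setMethod("show", "PeakSet", function(object) {
  cat(sprintf(
    "PeakSet: %d retained peaks (median prominence %.3g; FWHM >= %g nm, spacing >= %g nm)\n",
    nrow(object@peaks), object@median_prominence, object@min_fwhm_nm,
    object@min_spacing_nm))
})

setMethod("show", "DomainSegmentation", function(object) {
  cat(sprintf(
    "DomainSegmentation: %d dark / %d bright domains, crystallinity %.1f%%\n",
    length(object@dark_lengths_nm), length(object@bright_lengths_nm),
    object@crystallinity_pct))
})

setMethod("show", "Diffractogram1D", function(object) {
  cat(sprintf("Diffractogram1D: %d bins, 2theta %.1f-%.1f deg (lambda %.2f A)\n",
              length(object@twotheta_deg), min(object@twotheta_deg),
              max(object@twotheta_deg), object@wavelength_A))
})

setMethod("show", "CrystallinityResult", function(object) {
  cat(sprintf(
    "CrystallinityResult: crystallinity %.1f%% over [%g, %g] deg; %d peaks\n",
    object@crystallinity_pct, object@range_deg[1], object@range_deg[2],
    nrow(object@peaks)))
})

setMethod("show", "RamanSpectrum", function(object) {
  cat(sprintf("RamanSpectrum: %d samples, %.0f-%.0f cm^-1; %d processing steps\n",
              length(object@wavenumber_cm1), min(object@wavenumber_cm1),
              max(object@wavenumber_cm1), length(object@processing_log)))
})

setMethod("show", "TensileCurve", function(object) {
  cat(sprintf("TensileCurve: %d samples, max stress %.3g MPa at strain %.3g\n",
              length(object@strain), max(object@stress_MPa),
              object@strain[which.max(object@stress_MPa)]))
})

setMethod("show", "PellicleGeometry", function(object) {
  cat(sprintf(
    "PellicleGeometry: A %.1f mm^2, r %.1f mm, h %.2f mm, rho %.3g mg/cm^3\n",
    object@area_measured_mm2, object@container_radius_mm,
    object@equiv_height_mm, object@density_mg_cm3))
})
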