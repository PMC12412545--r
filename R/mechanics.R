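# Engineering stress-strain analysis of wet dogbone pellicle specimens.

#' Convert a raw tensile record to an engineering stress-strain curve
#'
#' Crops the record at the first sample reaching the minimum force onset
#' (2.5 mN), re-zeroes the displacement there, and converts displacement to
#' engineering strain (over the starting grip spacing) and force to
#' engineering stress (over width x thickness).
#'
#' @param displacement_mm monotone crosshead displacement record.
#' @param force_N matching force record in Newton.
#' @param geometry a \code{\link{dogboneGeometry}}.
#' @param onset_mN minimum onset force (default 2.5 mN).
#' @return A \code{TensileCurve}.
#' @export
loadCurve <- function(displacement_mm, force_N, geometry, onset_mN = 2.5) {
  stopifnot(is(geometry, "DogboneGeometry"),
            length(displacement_mm) == length(force_N))
  if (any(diff(displacement_mm) < 0)) stop("displacement must be monotone")
  first <- which(force_N >= onset_mN / 1000)[1]
  if (is.na(first))
    stop(sprintf("no sample reaches the %.1f mN onset; curve rejected", onset_mN))
  d <- displacement_mm[first:length(displacement_mm)]
  f <- force_N[first:length(force_N)]
  strain <- (d - d[1]) / geometry@gauge_length_mm
  stress <- f / (geometry@width_mm * geometry@thickness_mm)
  new("TensileCurve", strain = strain, stress_MPa = stress,
      onset_shift_applied = TRUE, geometry = geometry)
}

# First sample index after an abrupt rupture: stress falls below half the
# running maximum within 3 samples of that maximum. Drops while the running
# maximum is still a negligible fraction of the final stress level are
# measurement noise in the toe, not rupture. NA when no rupture.
.ruptureIndex <- function(stress) {
  cmax <- cummax(stress)
  imax <- cummax(seq_along(stress) * (stress == cmax))
  drop <- which(stress < 0.5 * cmax & (seq_along(stress) - imax) <= 3 &
                  cmax > 0.1 * max(stress))
  if (length(drop) == 0) NA_integer_ else drop[1]
}

# Index of maximum stress before rupture.
.peakIndex <- function(c) {
  stress <- curveStress(c)
  ri <- .ruptureIndex(stress)
  upto <- if (is.na(ri)) length(stress) else ri - 1L
  which.max(stress[seq_len(upto)])
}

#' Tensile modulus from the linear stress-strain window
#'
#' Least-squares slope of stress versus strain between 60\% and 80\% of the
#' strain at maximum stress.
#'
#' @param c a \code{\link{loadCurve}} result.
#' @param window fractions of the strain at maximum stress delimiting the
#'   fit window (default c(0.6, 0.8)).
#' @return Modulus in MPa.
#' @export
tensileModulus <- function(c, window = c(0.6, 0.8)) {
  stopifnot(is(c, "TensileCurve"))
  strain <- curveStrain(c); stress <- curveStress(c)
  emax <- strain[.peakIndex(c)]
  sel <- strain >= window[1] * emax & strain <= window[2] * emax
  if (sum(sel) < 5)
    stop(sprintf("modulus window holds only %d samples (need >= 5)", sum(sel)))
  as.numeric(coef(lm(stress[sel] ~ strain[sel]))[2])
}

#' Tensile strength of a specimen
#'
#' Maximum engineering stress reached before rupture. When no abrupt rupture
#' is detected (for example a test stopped early) the maximum stress of the
#' record is still returned, flagged accordingly.
#'
#' @param c a \code{\link{loadCurve}} result.
#' @return A list with \code{strength_MPa}, \code{strain_at_max},
#'   \code{rupture_detected} and \code{stress_at_rupture_MPa} (stress at the
#'   last sample before the rupture drop, identical to the maximum for an
#'   abrupt rupture).
#' @export
tensileStrength <- function(c) {
  stopifnot(is(c, "TensileCurve"))
  stress <- curveStress(c); strain <- curveStrain(c)
  ri <- .ruptureIndex(stress)
  ip <- .peakIndex(c)
  list(strength_MPa = stress[ip], strain_at_max = strain[ip],
       rupture_detected = !is.na(ri),
       stress_at_rupture_MPa = if (is.na(ri)) stress[length(stress)]
       else stress[ri - 1L])
}
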