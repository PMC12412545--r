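# Synthetic tensile curves and pellicle side-view photographs with stored
# ground truth.

#' Generate a raw tensile force-displacement record
#'
#' Produces an engineering stress-strain curve with a quadratic toe region
#' (slope rising smoothly to the target modulus at \code{toe_strain}), a
#' linear-elastic branch of exactly the requested modulus, and an abrupt
#' rupture when the stress reaches the requested strength; exported as
#' displacement and force through the dogbone geometry, with optional
#' Gaussian noise on the stress.
#'
#' @param modulus_MPa slope of the linear branch (> 0).
#' @param strength_MPa rupture stress (> 0).
#' @param toe_strain strain extent of the nonlinear toe (0 disables it).
#' @param noise_sd_MPa Gaussian stress noise SD.
#' @param seed integer seed.
#' @param geometry a \code{\link{dogboneGeometry}}.
#' @param n_samples number of samples up to rupture.
#' @return A list with \code{displacement_mm}, \code{force_N}, the noiseless
#'   \code{stress_MPa}/\code{strain} oracle curves, \code{geometry} and the
#'   requested truth values.
#' @export
genTensileCurve <- function(modulus_MPa, strength_MPa, toe_strain = 0.03,
                            noise_sd_MPa = 0, seed = 1,
                            geometry = dogboneGeometry(), n_samples = 2000) {
  stopifnot(modulus_MPa > 0, strength_MPa > 0, toe_strain >= 0)
  set.seed(seed)
  # linear branch: stress = E * (strain - toe/2) beyond the toe
  eps_rup <- strength_MPa / modulus_MPa + toe_strain / 2
  strain <- seq(0, eps_rup, length.out = n_samples)
  stress <- ifelse(strain < toe_strain & toe_strain > 0,
                   modulus_MPa * strain^2 / (2 * max(toe_strain, 1e-12)),
                   modulus_MPa * (strain - toe_strain / 2))
  stress[n_samples] <- strength_MPa
  # a few post-rupture samples near zero stress
  post_n <- 5L
  dstep <- strain[2] - strain[1]
  strain_all <- c(strain, eps_rup + dstep * seq_len(post_n))
  stress_all <- c(stress, rep(0.01 * strength_MPa, post_n))
  noisy <- stress_all + if (noise_sd_MPa > 0)
    rnorm(length(stress_all), sd = noise_sd_MPa) else 0
  area <- geometry@width_mm * geometry@thickness_mm
  list(displacement_mm = strain_all * geometry@gauge_length_mm,
       force_N = noisy * area,
       strain = strain_all, stress_MPa = stress_all,
       geometry = geometry,
       truth = list(modulus_MPa = modulus_MPa, strength_MPa = strength_MPa,
                    toe_strain = toe_strain, rupture_strain = eps_rup))
}

#' Generate a pellicle side-view photograph
#'
#' Renders the wet pellicle as a bright rectangle of width 2 r and the given
#' height on a dark background, with mild Gaussian noise; the true mask and
#' area are returned alongside.
#'
#' @param radius_mm container (pellicle) radius.
#' @param height_mm pellicle height.
#' @param scale_mm_per_px mm per pixel of the photograph.
#' @param seed integer seed.
#' @param noise_sd Gaussian noise SD in gray units (foreground 0.8,
#'   background 0.15).
#' @return A list with \code{photo} (matrix), \code{mask} (noiseless truth),
#'   \code{area_mm2} (true area 2 r h) and the inputs.
#' @export
genPelliclePhoto <- function(radius_mm = 20, height_mm = 5,
                             scale_mm_per_px = 0.1, seed = 1, noise_sd = 0.05) {
  stopifnot(radius_mm > 0, height_mm > 0, scale_mm_per_px > 0)
  set.seed(seed)
  w_px <- 2 * radius_mm / scale_mm_per_px
  h_px <- height_mm / scale_mm_per_px
  mx <- ceiling(0.15 * w_px); my <- ceiling(0.6 * h_px) + 5
  nx <- ceiling(w_px) + 2 * mx; ny <- ceiling(h_px) + 2 * my
  xs <- (seq_len(nx) - 0.5) * scale_mm_per_px
  ys <- (seq_len(ny) - 0.5) * scale_mm_per_px
  x0 <- mx * scale_mm_per_px; y0 <- my * scale_mm_per_px
  inx <- xs > x0 & xs <= x0 + 2 * radius_mm
  iny <- ys > y0 & ys <= y0 + height_mm
  mask <- outer(iny, inx, "&")
  photo <- ifelse(mask, 0.8, 0.15) +
    if (noise_sd > 0) matrix(rnorm(ny * nx, sd = noise_sd), ny, nx) else 0
  list(photo = photo, mask = mask, area_mm2 = sum(mask) * scale_mm_per_px^2,
       true_area_mm2 = 2 * radius_mm * height_mm,
       radius_mm = radius_mm, height_mm = height_mm,
       scale_mm_per_px = scale_mm_per_px)
}
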