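# Raman spectrum preprocessing (smoothing, polynomial background
# subtraction, normalization) and the carbonyl-band presence test.

# Piecewise polynomial background: degree-8 fits over ~window-sample spans,
# blended across seams with raised-cosine (Hann) tapers.
.polyBackground <- function(x, y, degree = 8, window = 256) {
  n <- length(y)
  if (n <= window) {
    fit <- lm(y ~ poly(x, degree))
    return(as.numeric(predict(fit)))
  }
  # 50% overlapping windows
  starts <- seq(1, n - window + 1, by = window %/% 2)
  if (tail(starts, 1) + window - 1 < n) starts <- c(starts, n - window + 1)
  bg <- numeric(n); wt <- numeric(n)
  for (s in starts) {
    idx <- s:(s + window - 1)
    fit <- lm(y[idx] ~ poly(x[idx], degree))
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(window) - 0.5) / window)
    bg[idx] <- bg[idx] + w * as.numeric(predict(fit))
    wt[idx] <- wt[idx] + w
  }
  bg / pmax(wt, .Machine$double.eps)
}

#' Normalize a Raman spectrum to its strongest cellulose band
#'
#' Divides the counts by the maximum within \code{center +/- halfwidth}
#' (default the 1094 1/cm glycosidic band). Applying the normalization twice
#' is identical to applying it once.
#'
#' @param s a \code{\link{ramanSpectrum}}.
#' @param center_cm1 reference band position (default 1094).
#' @param halfwidth_cm1 search half-window (default 10).
#' @return The normalized \code{RamanSpectrum} (step appended to the log).
#' @export
normalizeSpectrum <- function(s, center_cm1 = 1094, halfwidth_cm1 = 10) {
  stopifnot(is(s, "RamanSpectrum"))
  w <- wavenumbers(s)
  sel <- abs(w - center_cm1) <= halfwidth_cm1
  if (!any(sel)) stop("normalization window lies outside the spectrum grid")
  peak <- max(intensityValues(s)[sel])
  if (peak <= 0) stop("non-positive reference peak; cannot normalize")
  new("RamanSpectrum", wavenumber_cm1 = w,
      counts = intensityValues(s) / peak,
      processing_log = c(s@processing_log,
                         sprintf("normalize(center=%g,halfwidth=%g)",
                                 center_cm1, halfwidth_cm1)))
}

#' Preprocess a raw Raman spectrum
#'
#' Applies, in order: Savitzky-Golay smoothing (polynomial degree 7 over a
#' 13-point window; the customary 12-point setting is even, so the nearest
#' odd width is used and recorded in the log), piecewise polynomial
#' background subtraction (degree 8 over 256-point windows, cosine-blended at
#' the seams), and normalization to the strongest band at 1094 1/cm.
#' Reprocessing an already processed spectrum is rejected.
#'
#' @param raw a \code{\link{ramanSpectrum}} with an empty processing log and
#'   at least 256 samples.
#' @param sg_degree,sg_window Savitzky-Golay settings (window is rounded up
#'   to odd).
#' @param bg_degree,bg_window background-subtraction settings.
#' @param normalize_at_cm1 reference band for the final normalization.
#' @return The processed \code{RamanSpectrum}.
#' @export
preprocessSpectrum <- function(raw, sg_degree = 7, sg_window = 12,
                               bg_degree = 8, bg_window = 256,
                               normalize_at_cm1 = 1094) {
  stopifnot(is(raw, "RamanSpectrum"))
  if (length(processingLog(raw)) > 0)
    stop("spectrum has already been processed (see processingLog)")
  w <- wavenumbers(raw); y <- intensityValues(raw)
  if (length(y) < 256) stop("need at least 256 samples")
  nodd <- if (sg_window %% 2 == 0) sg_window + 1 else sg_window
  ysm <- signal::sgolayfilt(y, p = sg_degree, n = nodd)
  bg <- .polyBackground(w, ysm, degree = bg_degree, window = bg_window)
  out <- new("RamanSpectrum", wavenumber_cm1 = w, counts = ysm - bg,
             processing_log = c(
               sprintf("savitzky_golay(degree=%d,window=%d)", sg_degree, nodd),
               sprintf("poly_background(degree=%d,window=%d)", bg_degree,
                       bg_window)))
  normalizeSpectrum(out, center_cm1 = normalize_at_cm1)
}

#' Test for the presence of a band in a Raman spectrum
#'
#' Scores a candidate band (by default the acetylation carbonyl C=O stretch
#' near 1740 1/cm) as (maximum in the window minus the local baseline) over
#' the noise SD, both estimated from flanking regions; the band is declared
#' present when the score reaches 3.
#'
#' The local baseline is the mean of the flanking regions and the noise SD
#' is estimated from first differences of the flanks (insensitive to slow
#' baseline drift).
#'
#' @param s a \code{\link{ramanSpectrum}} (usually preprocessed).
#' @param center_cm1 band position (default 1740).
#' @param halfwidth_cm1 half-width of the search window (default 10).
#' @param threshold score needed to call the band present (default 3).
#' @return A list with \code{score}, \code{present}, \code{baseline} and
#'   \code{noise_sd}.
#' @export
detectBand <- function(s, center_cm1 = 1740, halfwidth_cm1 = 10,
                       threshold = 3) {
  stopifnot(is(s, "RamanSpectrum"))
  w <- wavenumbers(s); y <- intensityValues(s)
  if (center_cm1 - 8 * halfwidth_cm1 < min(w) ||
      center_cm1 + 8 * halfwidth_cm1 > max(w))
    stop("band window (with flanks) lies outside the spectrum grid")
  if (abs(center_cm1 - 1094) < halfwidth_cm1 + 10)
    warning("band window overlaps the normalization reference peak")
  inwin <- abs(w - center_cm1) <= halfwidth_cm1
  flank_l <- w < center_cm1 - halfwidth_cm1 &
    w >= center_cm1 - 8 * halfwidth_cm1
  flank_r <- w > center_cm1 + halfwidth_cm1 &
    w <= center_cm1 + 8 * halfwidth_cm1
  baseline <- mean(y[flank_l | flank_r])
  noise_sd <- sd(c(diff(y[flank_l]), diff(y[flank_r]))) / sqrt(2)
  score <- (max(y[inwin]) - baseline) / noise_sd
  list(score = score, present = score >= threshold, baseline = baseline,
       noise_sd = noise_sd)
}
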