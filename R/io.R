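# File-format plumbing: multi-page TIFF stacks, two-column CSV curves and
# spectra, JSON reports.

#' Read a multi-page TIFF stack into an array
#'
#' @param path TIFF file.
#' @return Numeric array (y, x, t).
#' @export
readTiffStack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' Write an array as a multi-page 32-bit float TIFF
#'
#' Values are written as-is (no rescaling) in floating point.
#'
#' @param arr numeric array (y, x, t) or matrix.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeTiffStack <- function(arr, path) {
  if (is.matrix(arr)) arr <- array(arr, dim = c(dim(arr), 1))
  pages <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read a two-column CSV (with header) as a list of vectors
#'
#' The standard on-disk form for diffractograms (twotheta_deg, intensity),
#' Raman spectra (wavenumber_cm1, counts) and tensile records
#' (displacement_mm, force_N).
#'
#' @param path CSV file with a header line and two numeric columns.
#' @return A named list of the two columns.
#' @export
readXYCSV <- function(path) {
  df <- read.csv(path)
  if (ncol(df) < 2) stop("expected two columns in ", path)
  as.list(df[, 1:2])
}

#' Write two vectors as a two-column CSV with a header
#'
#' @param x,y numeric vectors.
#' @param names column names.
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeXYCSV <- function(x, y, names, path) {
  df <- setNames(data.frame(x, y), names)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x a named list of results (scalars unboxed).
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeJSONReport <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
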