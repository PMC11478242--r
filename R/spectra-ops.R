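#' Normalize a spectrum to its base peak
#'
#' Rescales all intensities so the most intense peak (the base peak) equals
#' `scale`, the relative-abundance convention of EI-MS libraries.  Ratios
#' between peaks are preserved exactly.
#'
#' @param s A [mass_spectrum].
#' @param scale Target base-peak intensity (default 100).
#' @return The rescaled [mass_spectrum].
#' @export
normalize_base_peak <- function(s, scale = 100) {
  stopifnot(inherits(s, "mass_spectrum"), is.numeric(scale), scale > 0)
  top <- max(s$intensity)
  if (top <= 0) stop("cannot normalize an all-zero spectrum")
  s$intensity <- s$intensity * (scale / top)
  s
}

#' Crop a spectrum to an m/z window
#'
#' Retains peaks whose nominal mass (round-half-up of m/z) lies in
#' `[lo, hi]`, both bounds inclusive.  Low-mass fragments below m/z 40
#' carry little class information and masses above 300 are rare in this
#' compound space, hence the defaults.  A spectrum that loses all its peaks
#' is returned with an empty peak list and must be rejected downstream.
#'
#' @param s A [mass_spectrum].
#' @param lo,hi Integer window bounds, `lo < hi`.
#' @return The cropped [mass_spectrum] (possibly with zero peaks).
#' @export
crop_spectrum <- function(s, lo = 40L, hi = 300L) {
  stopifnot(inherits(s, "mass_spectrum"), lo < hi)
  nominal <- round_half_up(s$mz)
  keep <- nominal >= lo & nominal <= hi
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Bin a spectrum onto a unit-mass grid
#'
#' Low-resolution EI spectra are nominal-mass: every peak is assigned to
#' the integer bin `round_half_up(mz)`, and peaks rounding to the same
#' integer are summed.  The result is a dense intensity vector over
#' `lo:hi` (length `hi - lo + 1`; 261 channels for the default 40--300).
#'
#' @param s A [mass_spectrum], already cropped to `[lo, hi]`.
#' @param lo,hi Integer grid bounds.
#' @return Numeric vector of length `hi - lo + 1`, named by m/z.
#' @export
bin_to_unit_mass <- function(s, lo = 40L, hi = 300L) {
  stopifnot(inherits(s, "mass_spectrum"), lo < hi)
  v <- numeric(hi - lo + 1L)
  names(v) <- as.character(lo:hi)
  if (length(s$mz)) {
    idx <- round_half_up(s$mz) - lo + 1L
    if (any(idx < 1L | idx > length(v)))
      stop("spectrum has peaks outside [lo, hi]; crop first")
    tab <- tapply(s$intensity, idx, sum)
    v[as.integer(names(tab))] <- as.numeric(tab)
  }
  v
}
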