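#' Assemble a labeled spectral data matrix
#'
#' Runs every spectrum through the standard pipeline --- base-peak
#' normalization (on the full spectrum, so the base peak is defined before
#' any peak is discarded), cropping to `[lo, hi]`, unit-mass binning ---
#' and stacks the resulting vectors into an n x p intensity matrix with
#' row-matched class annotations.  Row order is the input order.
#'
#' @param spectra List of [mass_spectrum] objects.
#' @param annotations A [class_annotation] table covering every
#'   `compound_id` in `spectra` exactly once.
#' @param lo,hi Crop/bin bounds (default 40--300, p = 261 channels).
#' @param scale Base-peak normalization target.
#' @return An object of class `spectrum_matrix`: list with `X` (n x p
#'   matrix, rows named by compound id, columns by m/z), `mz_axis`,
#'   `sample_ids`, `annotations` (rows aligned with `X`).
#' @export
build_matrix <- function(spectra, annotations, lo = 40L, hi = 300L,
                         scale = 100) {
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  annotations <- validate_annotation(annotations)
  ids <- vapply(spectra, `[[`, "", "compound_id")
  if (anyDuplicated(ids))
    stop("duplicate compound_id in spectra: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(annotations$compound_id))
    stop("duplicate compound_id in annotations: ",
         paste(unique(annotations$compound_id[
           duplicated(annotations$compound_id)]), collapse = ", "))
  miss <- setdiff(ids, annotations$compound_id)
  if (length(miss))
    stop("no annotation for compound(s): ", paste(miss, collapse = ", "))
  rows <- lapply(spectra, function(s) {
    s <- crop_spectrum(normalize_base_peak(s, scale), lo, hi)
    if (length(s$mz) == 0L)
      stop("spectrum '", s$compound_id, "' has no peaks in [", lo, ", ", hi, "]")
    bin_to_unit_mass(s, lo, hi)
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  ann <- annotations[match(ids, annotations$compound_id), , drop = FALSE]
  rownames(ann) <- NULL
  structure(list(X = X, mz_axis = lo:hi, sample_ids = ids,
                 annotations = ann),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf(paste0("<spectrum_matrix> %d spectra x %d m/z channels ",
                     "(m/z %d-%d)\n"),
              nrow(x$X), ncol(x$X), min(x$mz_axis), max(x$mz_axis)))
  cat(sprintf("  cannabinoids: %d, other drugs: %d\n",
              sum(x$annotations$is_cannabinoid),
              sum(!x$annotations$is_cannabinoid)))
  invisible(x)
}

# Row-subset that keeps X and annotations aligned.
subset_matrix <- function(sm, idx) {
  structure(list(X = sm$X[idx, , drop = FALSE],
                 mz_axis = sm$mz_axis,
                 sample_ids = sm$sample_ids[idx],
                 annotations = sm$annotations[idx, , drop = FALSE]),
            class = "spectrum_matrix")
}
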