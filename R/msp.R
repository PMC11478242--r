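#' Construct a mass spectrum
#'
#' A `mass_spectrum` holds one compound's electron-ionization peak list at
#' whatever m/z resolution it was recorded.  Peaks are canonicalized on
#' construction: sorted by m/z, with peaks at exactly equal m/z summed, so
#' the stored m/z values are strictly increasing.
#'
#' @param compound_id Unique compound identifier (defaults to `name`).
#' @param name Compound name as given in the source library.
#' @param mz Numeric vector of mass-to-charge ratios, all positive.
#' @param intensity Numeric vector of non-negative intensities, same length
#'   as `mz`, with at least one positive value.
#' @param source Free-text provenance tag (e.g. `"training"`, `"test"`).
#' @return An object of class `mass_spectrum`: a list with elements
#'   `compound_id`, `name`, `mz`, `intensity`, `source`.
#' @examples
#' s <- mass_spectrum("JWH-018", mz = c(144, 214, 284, 341),
#'                    intensity = c(60, 100, 45, 30))
#' s
#' @export
mass_spectrum <- function(name, mz, intensity, compound_id = name,
                          source = "unknown") {
  stopifnot(is.character(name), length(name) == 1L)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) == 0L) stop("spectrum must contain at least one peak")
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("all m/z must be positive")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be non-negative")
  if (all(intensity == 0)) stop("at least one intensity must be positive")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
    mz <- unique(mz)
  }
  structure(list(compound_id = compound_id, name = name, mz = mz,
                 intensity = intensity, source = source),
            class = "mass_spectrum")
}

#' @export
print.mass_spectrum <- function(x, ...) {
  cat(sprintf("<mass_spectrum> %s (%d peaks, m/z %.1f-%.1f, base peak %.0f)\n",
              x$name, length(x$mz), min(x$mz), max(x$mz),
              x$mz[which.max(x$intensity)]))
  invisible(x)
}

# Nominal-mass assignment used throughout: round half UP, never half-even,
# so e.g. 144.5 -> 145 regardless of parity.
round_half_up <- function(x) floor(x + 0.5)

#' Read a NIST-style MSP spectral library
#'
#' Parses the plain-text MSP dialect used by EI-MS libraries: records
#' separated by blank lines, a `Name:` field, a `Num Peaks:` field, then
#' m/z--intensity pairs separated by whitespace and/or semicolons, possibly
#' several pairs per line.  Other header fields (`Comments:`, `Formula:`,
#' ...) are ignored, except `ID:` / `DB#:` which, when present, supply the
#' compound id.  A record whose parsed peak count disagrees with its
#' declared `Num Peaks` is rejected with a warning and parsing continues.
#'
#' @param path Path to an MSP text file.
#' @param source Provenance tag attached to every spectrum read.
#' @return A list of [mass_spectrum] objects, one per valid record.
#' @seealso [write_msp()]
#' @export
read_msp <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines))))
    stop("empty MSP file: ", path)
  blank <- !nzchar(trimws(lines))
  rec_id <- cumsum(c(TRUE, blank[-length(blank)] & !blank[-1L]))
  rec_id[blank] <- NA
  out <- list()
  for (ri in unique(rec_id[!is.na(rec_id)])) {
    rec <- lines[which(rec_id == ri & !is.na(rec_id))]
    sp <- parse_msp_record(rec, source)
    if (!is.null(sp)) out[[length(out) + 1L]] <- sp
  }
  if (length(out) == 0L) stop("no valid MSP records in ", path)
  out
}

parse_msp_record <- function(rec, source) {
  is_hdr <- grepl("^[A-Za-z][A-Za-z0-9 #_.-]*:", rec)
  hdr <- rec[is_hdr]
  key <- tolower(sub(":.*$", "", hdr))
  val <- trimws(sub("^[^:]*:", "", hdr))
  nm <- val[match("name", key)]
  np <- suppressWarnings(as.integer(val[match("num peaks", key)]))
  id <- val[match("id", key)]
  if (is.na(id)) id <- val[match("db#", key)]
  if (is.na(nm) || is.na(np)) {
    warning("MSP record without Name/Num Peaks skipped", call. = FALSE)
    return(NULL)
  }
  peak_lines <- rec[!is_hdr]
  tok <- unlist(strsplit(paste(peak_lines, collapse = " "), "[;,[:space:]]+"))
  tok <- tok[nzchar(tok)]
  num <- suppressWarnings(as.numeric(tok))
  if (anyNA(num) || length(num) %% 2L != 0L || length(num) / 2L != np) {
    warning(sprintf("MSP record '%s': %d peaks parsed but %d declared; skipped",
                    nm, length(num) %/% 2L, np), call. = FALSE)
    return(NULL)
  }
  m <- matrix(num, ncol = 2L, byrow = TRUE)
  tryCatch(
    mass_spectrum(nm, mz = m[, 1L], intensity = m[, 2L],
                  compound_id = if (is.na(id)) nm else id, source = source),
    error = function(e) {
      warning(sprintf("MSP record '%s' invalid (%s); skipped", nm,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
}

#' Write spectra to an MSP file
#'
#' Emits the same dialect [read_msp()] consumes; `read_msp(write_msp(...))`
#' round-trips peak lists exactly (up to numeric formatting at 10 digits).
#'
#' @param spectra A list of [mass_spectrum] objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_msp <- function(spectra, path) {
  if (inherits(spectra, "mass_spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(sprintf("Name: %s", s$name),
                 sprintf("ID: %s", s$compound_id),
                 sprintf("Num Peaks: %d", length(s$mz))), con)
    pairs <- sprintf("%.10g %.10g", s$mz, s$intensity)
    idx <- split(pairs, (seq_along(pairs) - 1L) %/% 5L)
    writeLines(vapply(idx, paste, "", collapse = "; "), con)
    writeLines("", con)
  }
  invisible(path)
}
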