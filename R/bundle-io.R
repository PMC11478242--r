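#' Save / load a trained cascade bundle
#'
#' Bundles are stored as structured JSON text
#' ([jsonlite::serializeJSON()], which round-trips every numeric array,
#' mask, threshold and configuration field exactly).  The file embeds
#' the training seed, configuration and a training-data checksum, so any
#' run is reproducible from its saved output.  Saving the same bundle
#' twice produces byte-identical files.
#'
#' @param bundle A trained [train_cascade()] object.
#' @param path File path (conventionally `*.json`).
#' @return `save_bundle`: `path`, invisibly.  `load_bundle`: the
#'   restored `eims_cascade` object.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "eims_cascade"))
  txt <- jsonlite::serializeJSON(bundle, digits = NA)
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_bundle
#' @export
load_bundle <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bundle <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                            collapse = "\n"))
  if (!inherits(bundle, "eims_cascade"))
    stop("file does not contain an eims_cascade bundle: ", path)
  bundle
}
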