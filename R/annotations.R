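CORE_GROUPS <- c("indole", "indazole", "azaindole", "naphthoylpyrrole",
                 "other", "n/a")

ANNOTATION_COLS <- c("compound_id", "is_cannabinoid", "is_classical",
                     "core_group", "head_is_naphthyl", "tail_is_fub",
                     "tail_is_5f_pentyl")

#' Class annotations for the decision cascade
#'
#' Builds the per-compound label table that drives training and evaluation
#' of every cascade node.  One row per compound; columns:
#' \describe{
#'   \item{compound_id}{unique identifier matching the spectra}
#'   \item{is_cannabinoid}{logical; positive class of the root node}
#'   \item{is_classical}{logical, `NA` for non-cannabinoids: classical
#'     (THC-related tricyclic) vs synthetic cannabinoid}
#'   \item{core_group}{one of `"indole"`, `"indazole"`, `"azaindole"`,
#'     `"naphthoylpyrrole"`, `"other"`, `"n/a"`; `"n/a"` for anything that
#'     is not a synthetic cannabinoid}
#'   \item{head_is_naphthyl, tail_is_fub, tail_is_5f_pentyl}{logical,
#'     `NA` when not applicable (non-synthetics and, by default, the
#'     naphthoylpyrrole-core compounds, which the head/tail nodes never
#'     see)}
#' }
#' Unknown or not-applicable labels are always an explicit `NA`, never a
#' default class.  Subgroup fields may only be set for cannabinoids
#' (`is_classical`) or synthetic cannabinoids (core/head/tail).
#'
#' @param compound_id Character vector of compound ids.
#' @param is_cannabinoid Logical vector.
#' @param is_classical,head_is_naphthyl,tail_is_fub,tail_is_5f_pentyl
#'   Logical vectors, `NA` where not applicable.
#' @param core_group Character vector over the allowed core labels.
#' @return A validated `data.frame` of class `class_annotation`.
#' @export
class_annotation <- function(compound_id, is_cannabinoid,
                             is_classical = NA, core_group = "n/a",
                             head_is_naphthyl = NA, tail_is_fub = NA,
                             tail_is_5f_pentyl = NA) {
  ann <- data.frame(compound_id = as.character(compound_id),
                    is_cannabinoid = as.logical(is_cannabinoid),
                    is_classical = as.logical(is_classical),
                    core_group = as.character(core_group),
                    head_is_naphthyl = as.logical(head_is_naphthyl),
                    tail_is_fub = as.logical(tail_is_fub),
                    tail_is_5f_pentyl = as.logical(tail_is_5f_pentyl),
                    stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  stopifnot(is.data.frame(ann))
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols))
    stop("annotation table lacks columns: ", paste(missing_cols, collapse = ", "))
  ann <- ann[ANNOTATION_COLS]
  if (anyNA(ann$is_cannabinoid)) stop("is_cannabinoid must be TRUE/FALSE")
  bad <- !ann$core_group %in% CORE_GROUPS
  if (any(bad))
    stop("invalid core_group value(s): ",
         paste(unique(ann$core_group[bad]), collapse = ", "))
  # subgroup labels only where the cascade can reach them
  if (any(!ann$is_cannabinoid & !is.na(ann$is_classical)))
    stop("is_classical set for a non-cannabinoid")
  synth <- ann$is_cannabinoid & !is.na(ann$is_classical) & !ann$is_classical
  deeper <- ann$core_group != "n/a" | !is.na(ann$head_is_naphthyl) |
    !is.na(ann$tail_is_fub) | !is.na(ann$tail_is_5f_pentyl)
  if (any(deeper & !synth))
    stop("core/head/tail labels set for compounds that are not synthetic ",
         "cannabinoids: ",
         paste(ann$compound_id[deeper & !synth], collapse = ", "))
  class(ann) <- c("class_annotation", "data.frame")
  ann
}

#' Read / write a class-annotation table
#'
#' CSV with exactly the [class_annotation] columns; logical fields written
#' as `TRUE`/`FALSE` with empty cells for `NA`.
#'
#' @param path CSV file path.
#' @return `read_annotations`: a validated `class_annotation` data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ann <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(compound_id = "character",
                                        core_group = "character"))
  for (col in setdiff(ANNOTATION_COLS, c("compound_id", "core_group")))
    ann[[col]] <- as.logical(ann[[col]])
  validate_annotation(ann)
}

#' @rdname read_annotations
#' @param ann A `class_annotation` data.frame.
#' @export
write_annotations <- function(ann, path) {
  ann <- validate_annotation(ann)
  utils::write.csv(ann, path, row.names = FALSE, na = "")
  invisible(path)
}
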