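#' Per-node figures of merit for a trained cascade
#'
#' Builds the standard merit table: for every cascade node, one row each
#' for calibration (refit-free predictions on the training matrix),
#' venetian-blinds cross-validation (scaling, PLS and threshold
#' re-estimated per fold with the node's variable mask held fixed) and
#' external validation on a disjoint test matrix, reporting accuracy,
#' TPR, TNR, F1 and MCC plus the misclassified compound ids.  Cells
#' whose class is absent (or whole rows for skipped nodes) are `NA`.
#'
#' @param bundle A trained [train_cascade()] object.
#' @param cal The calibration (training) `spectrum_matrix`; when `NULL`
#'   the calibration and cross-validation rows are taken from the
#'   confusion matrices recorded at training time (misclassified ids
#'   are then unavailable).
#' @param test The external-validation `spectrum_matrix`; its compounds
#'   should be disjoint from the training set.
#' @return `data.frame` with `nodes x 3` rows: `node`, `set`, `n_pos`,
#'   `n_neg`, the five merit columns, and `misclassified`
#'   (semicolon-separated ids).
#' @export
evaluate_bundle <- function(bundle, cal = NULL, test) {
  stopifnot(inherits(bundle, "eims_cascade"))
  defs <- node_defs()
  k <- attr(bundle$config, "cv_folds")
  out <- list()
  for (nm in CASCADE_NODES) {
    nd <- bundle$nodes[[nm]]
    pos <- bundle$config[[nm]]$positive
    for (set in c("calibration", "cross-validation", "external validation")) {
      row <- data.frame(node = nm, set = set, n_pos = NA_integer_,
                        n_neg = NA_integer_, accuracy = NA_real_,
                        TPR = NA_real_, TNR = NA_real_, F1 = NA_real_,
                        MCC = NA_real_, misclassified = NA_character_,
                        stringsAsFactors = FALSE)
      if (!is.null(nd) && isTRUE(nd$available) &&
          is.null(cal) && set != "external validation") {
        cm <- if (set == "calibration") nd$calibration else nd$cross_validation
        m <- merit_row(cm)
        row$n_pos <- cm$TP + cm$FN
        row$n_neg <- cm$TN + cm$FP
        row[names(m)] <- as.list(m)
        out[[length(out) + 1L]] <- row
        next
      }
      if (!is.null(nd) && isTRUE(nd$available)) {
        sm <- if (set == "external validation") test else cal
        labs <- defs[[nm]]$labeller(sm$annotations)
        idx <- which(!is.na(labs))
        if (length(idx)) {
          X <- sm$X[idx, , drop = FALSE]
          truth <- labs[idx]
          ids <- sm$sample_ids[idx]
          if (set == "cross-validation") {
            cm <- cv_confusion(X, truth, pos, nd$classifier$variable_mask,
                               bundle$config[[nm]]$n_lv, k)
            pred <- attr(cm, "pred")
          } else {
            pred <- predict(nd$classifier, X)$label
            cm <- confusion(truth, pred, pos)
          }
          m <- merit_row(cm)
          row$n_pos <- sum(truth == pos)
          row$n_neg <- sum(truth != pos)
          row[names(m)] <- as.list(m)
          wrong <- ids[pred != truth]
          row$misclassified <- if (length(wrong))
            paste(wrong, collapse = ";") else ""
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
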