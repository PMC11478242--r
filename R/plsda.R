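#' Fit a binary PLS-DA classifier
#'
#' The workhorse behind each cascade node: codes the two classes +1/-1,
#' autoscales the predictors (dropping zero-variance channels),
#' optionally runs genetic-algorithm variable selection, fits a NIPALS
#' PLS model on the retained channels, and places the decision threshold
#' at the Gaussian crossing of the two classes' training scores.  A
#' sample scoring at or above the threshold is assigned the positive
#' label (ties go positive, a documented convention).
#'
#' @param X Raw (unscaled) n x p intensity matrix; columns are m/z
#'   channels when `mz_axis` is supplied.
#' @param labels Character/factor vector of length n with exactly two
#'   distinct values.
#' @param positive Which label is the positive (+1) class.
#' @param n_lv Number of latent variables.
#' @param use_ga Run GA variable selection before the final fit?
#' @param ga_config A [ga_config()] list (used when `use_ga = TRUE`).
#' @param mz_axis Optional integer vector naming the p columns (defaults
#'   to `40:300` when p = 261, else `1:p`).
#' @param seed Integer seed controlling the GA search.
#' @return Object of class `plsda`: the fitted `pls_model`, the
#'   `scaling_model`, `variable_mask` (length p, on the original column
#'   space), `threshold`, labels, `mz_axis`, and (when GA ran)
#'   the `ga_result`.
#' @seealso [predict.plsda()], [lv_weights()], [run_ga()]
#' @export
plsda <- function(X, labels, positive, n_lv = 2L, use_ga = FALSE,
                  ga_config = NULL, mz_axis = NULL, seed = 1L) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  lv <- unique(labels)
  if (length(lv) != 2L)
    stop("labels must take exactly 2 values, got: ",
         paste(lv, collapse = ", "))
  if (!positive %in% lv) stop("positive label '", positive, "' not in labels")
  negative <- setdiff(lv, positive)
  y <- ifelse(labels == positive, 1, -1)
  if (is.null(mz_axis))
    mz_axis <- if (ncol(X) == 261L) 40:300 else seq_len(ncol(X))
  stopifnot(length(mz_axis) == ncol(X))

  scaling <- autoscale_fit(X)
  Z <- autoscale_apply(scaling, X)
  kept_mz <- mz_axis[scaling$kept_mask]

  ga_result <- NULL
  sel <- rep(TRUE, ncol(Z))
  if (use_ga) {
    if (is.null(ga_config)) ga_config <- make_ga_config(n_lv = n_lv)
    ga_config$n_lv <- n_lv
    ga_result <- run_ga(Z, y, ga_config, seed = seed)
    sel <- ga_result$best_mask
  }
  n_lv_fit <- min(n_lv, sum(sel), nrow(Z) - 1L)
  pls <- fit_pls(Z[, sel, drop = FALSE], y, n_lv_fit)
  n_lv_fit <- pls$n_lv   # may truncate when X/y are exhausted early
  threshold <- fit_threshold(pls$fitted[y > 0], pls$fitted[y < 0])

  variable_mask <- logical(ncol(X))
  variable_mask[which(scaling$kept_mask)[sel]] <- TRUE
  structure(list(pls = pls, scaling = scaling, selected = sel,
                 variable_mask = variable_mask, threshold = threshold,
                 positive_label = positive, negative_label = negative,
                 n_lv = n_lv_fit, mz_axis = mz_axis, kept_mz = kept_mz[sel],
                 ga_result = ga_result, n_train = nrow(X)),
            class = "plsda")
}

#' Predict classes and discrimination scores
#'
#' Applies the classifier's stored autoscaling and variable mask to new
#' raw intensity rows, computes the PLS discrimination score, and labels
#' each row positive iff its score is `>=` the decision threshold.
#'
#' @param object A fitted [plsda()] classifier.
#' @param newdata Raw intensity matrix with the training column count.
#' @param ... Unused.
#' @return `data.frame` with columns `label` and `score`.
#' @export
predict.plsda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Z <- autoscale_apply(object$scaling, newdata)
  sc <- predict(object$pls, Z[, object$selected, drop = FALSE])
  data.frame(label = ifelse(sc >= object$threshold, object$positive_label,
                            object$negative_label),
             score = sc, row.names = rownames(newdata),
             stringsAsFactors = FALSE)
}

#' @export
coef.plsda <- function(object, ...) {
  b <- numeric(length(object$variable_mask))
  names(b) <- as.character(object$mz_axis)
  b[object$variable_mask] <- object$pls$reg_coef
  b
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("<plsda> %s (+) vs %s (-): %d LV, %d/%d m/z channels%s\n",
              x$positive_label, x$negative_label, x$n_lv,
              sum(x$variable_mask), length(x$variable_mask),
              if (is.null(x$ga_result)) "" else " (GA-selected)"))
  cat(sprintf("  threshold %.4f, trained on %d spectra\n",
              x$threshold, x$n_train))
  invisible(x)
}

#' Report the dominant m/z weights of a latent variable
#'
#' Maps the requested latent variable's weight vector back to m/z
#' through the classifier's variable mask and ranks channels by absolute
#' weight.  Signs are retained: channels whose weight sign matches the
#' positive class's side of the score axis pull predictions toward that
#' class, so the report reads as a fragment-ion interpretation of the
#' model.
#'
#' @param object A fitted [plsda()] classifier (or a `pls_model` plus
#'   explicit `mz`).
#' @param lv Latent-variable index, `1 <= lv <= n_lv`.
#' @param top_k How many channels to report; capped at the number of
#'   active channels (no padding).
#' @return `data.frame` with columns `mz` and `weight`, sorted by
#'   decreasing `abs(weight)`.
#' @export
lv_weights <- function(object, lv = 1L, top_k = 10L) {
  if (inherits(object, "plsda")) {
    m <- object$pls; mz <- object$kept_mz
  } else {
    m <- object; mz <- seq_len(nrow(m$weights))
  }
  if (lv < 1L || lv > m$n_lv)
    stop("lv must be in [1, ", m$n_lv, "]")
  w <- m$weights[, lv]
  o <- order(abs(w), decreasing = TRUE)
  o <- o[seq_len(min(top_k, length(o)))]
  data.frame(mz = mz[o], weight = w[o], row.names = NULL)
}
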