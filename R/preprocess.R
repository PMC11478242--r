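#' Fit an autoscaling model
#'
#' Computes per-column means and sample standard deviations (n-1
#' denominator, the chemometrics convention).  Columns whose standard
#' deviation falls below `1e-12` carry no information after scaling and
#' are flagged out of `kept_mask`; they are removed, not epsilon-padded,
#' and prediction data are reduced identically.
#'
#' @param X Numeric matrix, n >= 2 rows.
#' @return An object of class `scaling_model`: list with `means`, `stds`,
#'   `kept_mask` (all length p).
#' @export
autoscale_fit <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("autoscaling needs at least 2 rows")
  means <- colMeans(X)
  stds <- apply(X, 2L, stats::sd)
  structure(list(means = means, stds = stds, kept_mask = stds >= 1e-12),
            class = "scaling_model")
}

#' Apply (or invert) an autoscaling model
#'
#' Training-set means and standard deviations are applied unchanged to any
#' new matrix: `(x - mean) / sd` on kept columns, dropped columns removed.
#'
#' @param model A `scaling_model` from [autoscale_fit()].
#' @param X Matrix with the same column count the model was fitted on.
#' @return Matrix with `sum(model$kept_mask)` columns.
#' @export
autoscale_apply <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$means))
    stop("matrix has ", ncol(X), " columns but scaling model expects ",
         length(model$means))
  k <- model$kept_mask
  sweep(sweep(X[, k, drop = FALSE], 2L, model$means[k], "-"),
        2L, model$stds[k], "/")
}

#' @rdname autoscale_apply
#' @param Z Autoscaled matrix (kept columns only) to map back to the
#'   original intensity scale; dropped columns are restored at their
#'   training means.
#' @export
autoscale_invert <- function(model, Z) {
  Z <- as.matrix(Z)
  k <- model$kept_mask
  if (ncol(Z) != sum(k))
    stop("matrix has ", ncol(Z), " columns but scaling model kept ", sum(k))
  X <- matrix(rep(model$means, each = nrow(Z)), nrow = nrow(Z))
  X[, k] <- sweep(sweep(Z, 2L, model$stds[k], "*"), 2L, model$means[k], "+")
  colnames(X) <- names(model$means)
  X
}

#' Venetian-blinds cross-validation folds
#'
#' Deterministic interleaved assignment: sample `i` (0-based, in dataset
#' order) goes to fold `i mod k`.  With ordered data every fold samples
#' the sequence evenly --- the standard chemometrics splitter.
#'
#' @param n Number of samples.
#' @param k Number of splits (default 10).
#' @return Object of class `cv_folds`: list with `k` and `assignments`
#'   (length n, values `0:(k-1)`).
#' @export
venetian_blinds <- function(n, k = 10L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("need n >= k samples for ", k, " splits (got n = ", n, ")")
  structure(list(k = k, assignments = (seq_len(n) - 1L) %% k),
            class = "cv_folds")
}
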