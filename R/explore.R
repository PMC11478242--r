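#' PCA scores on an autoscaled matrix
#'
#' Exploratory principal-component scores (singular value decomposition
#' via [stats::prcomp()]) with a fixed sign convention: each component is
#' flipped, if necessary, so its largest-magnitude loading is positive,
#' making score plots reproducible across platforms.
#'
#' @param X Autoscaled numeric matrix.
#' @param k Number of components, `k <= min(n-1, p)`.
#' @return List with `scores` (n x k), `loadings` (p x k) and
#'   `explained` (length k, fractions of total variance, non-increasing).
#' @export
pca_scores <- function(X, k = 2L) {
  X <- as.matrix(X)
  k <- as.integer(k)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k < 1L || k > kmax) stop("k must be in [1, ", kmax, "]")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2L, flip, "*")
  list(scores = scores, loadings = loadings,
       explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2))
}

#' Ward hierarchical clustering of spectra
#'
#' Agglomerative clustering under Ward's minimum-variance criterion
#' (Lance--Williams recursion, [stats::hclust()] method `"ward.D2"` on
#' Euclidean distances), the standard dendrogram view for grouping
#' compound classes by spectral similarity.
#'
#' @param X Autoscaled numeric matrix, n >= 2 rows.
#' @return An [stats::hclust] tree; merge heights are non-decreasing.
#' @export
ward_hca <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  stats::hclust(stats::dist(X), method = "ward.D2")
}
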