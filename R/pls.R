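#' Fit a PLS1 regression by NIPALS
#'
#' Univariate-response partial least squares, the engine behind every
#' node of the decision cascade.  `X` is expected on the autoscaled
#' scale; both `X` and `y` are additionally mean-centered internally so
#' the same code serves cross-validation subsets.  Per component:
#' weight from the X'y covariance (normalized), score, X- and
#' y-loadings, then deflation of both blocks.  The sign of each
#' component is fixed by forcing its largest-magnitude X-loading
#' positive, so weight reports are reproducible.  If the deflated
#' blocks are exhausted before `n_lv` components (e.g. the response is
#' already fitted exactly), the model truncates to the achieved number,
#' reported in its `n_lv` field.
#'
#' @param X Numeric matrix (n x p), autoscaled.
#' @param y Numeric response; for discriminant analysis the +1/-1 class
#'   coding.
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(n-1, p)`.
#' @return Object of class `pls_model`: `weights` (p x A), `x_loadings`
#'   (p x A), `y_loadings` (length A), `scores` (n x A), `reg_coef`
#'   (length p), `intercept`, `x_means`, `y_mean`, `fitted`, `n_lv`.
#' @export
fit_pls <- function(X, y, n_lv) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  n_lv <- as.integer(n_lv)
  if (n_lv < 1L || n_lv > min(n - 1L, p))
    stop("n_lv must be in [1, min(n-1, p)] = [1, ", min(n - 1L, p), "]")
  if (stats::sd(y) < 1e-12) stop("response has zero variance")

  x_means <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_means)   # deflated X block
  f <- y - y_mean              # deflated y block
  W <- P <- matrix(0, p, n_lv)
  Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {
      # X or y exhausted (e.g. the response is already fit exactly):
      # keep the components obtained so far rather than failing
      if (a == 1L) stop("no covariance between X and y; cannot fit")
      n_lv <- a - 1L
      W <- W[, seq_len(n_lv), drop = FALSE]
      P <- P[, seq_len(n_lv), drop = FALSE]
      Tm <- Tm[, seq_len(n_lv), drop = FALSE]
      q <- q[seq_len(n_lv)]
      break
    }
    w <- w / wn
    t_a <- E %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(E, t_a) / tt
    q_a <- sum(f * t_a) / tt
    j <- which.max(abs(p_a))
    if (p_a[j] < 0) { w <- -w; t_a <- -t_a; p_a <- -p_a; q_a <- -q_a }
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
  }
  # regression vector in the (centered) X space: B = W (P'W)^-1 q
  B <- as.numeric(W %*% solve(crossprod(P, W), q))
  intercept <- y_mean - sum(x_means * B)
  fitted <- as.numeric(X %*% B) + intercept
  structure(list(n_lv = n_lv, weights = W, x_loadings = P, y_loadings = q,
                 scores = Tm, reg_coef = B, intercept = intercept,
                 x_means = x_means, y_mean = y_mean, fitted = fitted),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$reg_coef))
    stop("newdata has ", ncol(newdata), " columns, model expects ",
         length(object$reg_coef))
  as.numeric(newdata %*% object$reg_coef) + object$intercept
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variable(s), %d predictors\n",
              x$n_lv, length(x$reg_coef)))
  invisible(x)
}

#' Gaussian-crossing decision threshold
#'
#' Given the predicted discrimination scores of the two training classes,
#' fits one Gaussian per class and returns the score at which the two
#' densities are equal under equal priors (the Bayes boundary).  When
#' either class variance collapses (< 1e-12) or no density crossing lies
#' strictly between the class means, the midpoint of the two class means
#' is used instead; identical score distributions trigger the midpoint
#' with a warning.
#'
#' @param scores_pos,scores_neg Numeric score vectors of the positive and
#'   negative training class (both non-empty).
#' @return A single numeric threshold.
#' @export
fit_threshold <- function(scores_pos, scores_neg) {
  if (!length(scores_pos) || !length(scores_neg))
    stop("both classes need at least one score")
  m1 <- mean(scores_pos); m2 <- mean(scores_neg)
  v1 <- if (length(scores_pos) > 1L) stats::var(scores_pos) else 0
  v2 <- if (length(scores_neg) > 1L) stats::var(scores_neg) else 0
  midpoint <- (m1 + m2) / 2
  if (isTRUE(all.equal(m1, m2)) && isTRUE(all.equal(v1, v2))) {
    warning("identical class score distributions; threshold at midpoint")
    return(midpoint)
  }
  if (v1 < 1e-12 || v2 < 1e-12) return(midpoint)
  lo <- min(m1, m2); hi <- max(m1, m2)
  # equal-density condition: quadratic in x
  A <- 1 / (2 * v2) - 1 / (2 * v1)
  B <- m1 / v1 - m2 / v2
  C <- m2^2 / (2 * v2) - m1^2 / (2 * v1) + 0.5 * log(v2 / v1)
  roots <- if (abs(A) < 1e-12 * max(abs(B), 1)) {
    if (abs(B) < 1e-300) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0)
    else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  roots <- roots[roots > lo & roots < hi]
  if (!length(roots)) return(midpoint)
  roots[which.min(abs(roots - midpoint))]
}
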