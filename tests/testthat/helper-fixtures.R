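# Shared fixtures and independent oracles for the test suite.

NODE_NAMES <- c("cannabinoid_vs_other", "classical_vs_synthetic",
                "naphthoylpyrrole_vs_rest", "indole_vs_indazole_azaindole",
                "naphthyl_head", "fub_tail", "f5_pentyl_tail")

# cascade configuration with GA disabled at every node (fast unit tests
# of training/routing mechanics that do not exercise variable selection)
no_ga_config <- function(...) {
  ov <- setNames(lapply(NODE_NAMES, function(n) list(use_ga = FALSE)),
                 NODE_NAMES)
  do.call(cascade_config, c(ov, list(...)))
}

# small noiseless dataset shared across test files (built once per run)
tiny_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(sim_config(n_train = 6L, n_test = 4L,
                                            jitter_sigma = 0, dropout = 0,
                                            n_noise_peaks = 0L, seed = 11L))
    cache
  }
})

random_spectrum <- function(n_peaks = 20L, lo = 40, hi = 300) {
  mz <- sort(sample(seq(lo, hi), n_peaks)) + stats::runif(n_peaks, -0.4, 0.4)
  mass_spectrum(name = "rand", mz = mz,
                intensity = stats::runif(n_peaks, 1, 100))
}

# independent brute-force Ward clustering: greedy merge of the cluster
# pair with the smallest increase in total within-cluster sum of squares
brute_ward <- function(X) {
  cl <- lapply(seq_len(nrow(X)), identity)
  sse <- function(idx) {
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }
  merges <- list()
  heights <- numeric(0)
  while (length(cl) > 1L) {
    best <- NULL; bestd <- Inf
    for (i in 1:(length(cl) - 1L)) for (j in (i + 1L):length(cl)) {
      d <- sse(c(cl[[i]], cl[[j]])) - sse(cl[[i]]) - sse(cl[[j]])
      if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
    }
    merged <- sort(c(cl[[best[1L]]], cl[[best[2L]]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, bestd)
    cl <- c(cl[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# cluster membership after each hclust merge step, for comparison with
# brute_ward
hclust_partitions <- function(hc) {
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    members[[k]] <- sort(c(get(hc$merge[k, 1L]), get(hc$merge[k, 2L])))
  }
  members
}

# planted-signal GA fixture: 3 informative columns among 261
planted_signal <- function(seed = 99L, n = 60L, p = 261L,
                           info = c(50L, 120L, 200L), sigma = 0.3) {
  set.seed(seed)
  y <- rep(c(1, -1), each = n / 2)
  X <- matrix(stats::rnorm(n * p), n)
  for (j in info) X[, j] <- y + stats::rnorm(n, 0, sigma)
  sc <- autoscale_fit(X)
  list(Z = autoscale_apply(sc, X), y = y, info = info)
}
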