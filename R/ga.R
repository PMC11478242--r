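#' Genetic-algorithm configuration
#'
#' Hyperparameters of the variable-selection GA.  Defaults follow the
#' standard chemometrics setup for m/z selection: population 64, window
#' width 1 (each gene is a single m/z channel), mutation rate 0.005, at
#' most 50 generations, double-point crossover, tournament selection of
#' size 2, elitism of 1 and an initial inclusion probability of 0.3.
#' The search stops early when the best fitness has not improved for
#' `stall_limit` generations --- the automated stand-in for manually
#' monitoring GA convergence, which guards against over-selection when
#' runs are pushed past convergence.
#'
#' @param population_size Even integer, number of chromosomes.
#' @param window_width Variables controlled per gene (1 = per-channel).
#' @param mutation_rate Per-gene flip probability in (0, 1).
#' @param max_generations Generation cap, in `[1, 500]`.
#' @param init_inclusion_prob Probability a gene starts switched on.
#' @param n_lv Latent variables used inside the fitness CV.
#' @param cv_folds Venetian-blinds splits for the fitness.
#' @param tournament_size Parents compete in groups of this size.
#' @param elitism Number of best chromosomes copied unchanged.
#' @param stall_limit Early-stop patience (`Inf` disables).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 64L, window_width = 1L,
                      mutation_rate = 0.005, max_generations = 50L,
                      init_inclusion_prob = 0.3, n_lv = 2L, cv_folds = 10L,
                      tournament_size = 2L, elitism = 1L,
                      stall_limit = 10L) {
  cfg <- list(population_size = as.integer(population_size),
              window_width = as.integer(window_width),
              mutation_rate = mutation_rate,
              max_generations = as.integer(max_generations),
              init_inclusion_prob = init_inclusion_prob,
              n_lv = as.integer(n_lv), cv_folds = as.integer(cv_folds),
              tournament_size = as.integer(tournament_size),
              elitism = as.integer(elitism), stall_limit = stall_limit)
  if (cfg$population_size < 2L || cfg$population_size %% 2L != 0L)
    stop("population_size must be an even integer >= 2")
  if (cfg$mutation_rate <= 0 || cfg$mutation_rate >= 1)
    stop("mutation_rate must be in (0, 1)")
  if (cfg$window_width < 1L) stop("window_width must be >= 1")
  if (cfg$max_generations < 1L || cfg$max_generations > 500L)
    stop("max_generations must be in [1, 500]")
  if (cfg$init_inclusion_prob <= 0 || cfg$init_inclusion_prob > 1)
    stop("init_inclusion_prob must be in (0, 1]")
  class(cfg) <- "ga_config"
  cfg
}

make_ga_config <- ga_config

#' Expand a gene vector to a variable mask
#'
#' Each gene switches a contiguous block of `window_width` variables;
#' width 1 is the identity mapping.  The last block is truncated when
#' `p` is not a multiple of the width.
#'
#' @param genes Logical gene vector.
#' @param window_width Block size per gene.
#' @param p Target mask length (default: full blocks).
#' @return Logical vector of length `p`.
#' @export
window_expand <- function(genes, window_width, p = length(genes) * window_width) {
  stopifnot(window_width >= 1L)
  rep(as.logical(genes), each = window_width)[seq_len(p)]
}

#' Cross-validated fitness of a variable mask
#'
#' Fitness is the root-mean-squared error of cross-validated PLS-DA
#' discrimination scores against the +1/-1 class coding (RMSECV),
#' computed over the supplied venetian-blinds folds with only the masked
#' columns; lower is better.  An empty mask (or one on which the PLS
#' decomposition fails) scores `+Inf` and is never selected.
#'
#' @param mask Logical column mask over `X`.
#' @param X Autoscaled matrix.
#' @param y +1/-1 coded response.
#' @param n_lv Latent variables (reduced automatically when the masked
#'   column count or fold size cannot support it).
#' @param folds A [venetian_blinds()] assignment for `nrow(X)`.
#' @return A single numeric RMSECV (possibly `Inf`).
#' @export
ga_fitness <- function(mask, X, y, n_lv, folds) {
  mask <- as.logical(mask)
  if (!any(mask)) return(Inf)
  Xm <- X[, mask, drop = FALSE]
  press <- 0
  for (f in seq_len(folds$k) - 1L) {
    test <- folds$assignments == f
    ntr <- sum(!test)
    a <- min(n_lv, ncol(Xm), ntr - 1L)
    fit <- tryCatch(fit_pls(Xm[!test, , drop = FALSE], y[!test], a),
                    error = function(e) NULL)
    if (is.null(fit)) return(Inf)
    pred <- predict(fit, Xm[test, , drop = FALSE])
    press <- press + sum((y[test] - pred)^2)
  }
  sqrt(press / length(y))
}

#' Run the genetic-algorithm variable search
#'
#' Generational GA over binary m/z masks minimizing [ga_fitness()]:
#' rank the population, copy the elite unchanged, refill by double-point
#' crossover of tournament-selected parents, mutate each gene
#' independently.  Ranking applies a one-standard-error-style parsimony
#' rule: RMSECV values within a 2% relative band count as ties and are
#' resolved toward the smaller variable set, so converged runs keep
#' pruning channels that only fit fold noise.  Fully reproducible: the
#' same data, configuration and seed give the identical result.  As a
#' guard against over-selection, if the final best mask
#' cross-validates worse than using every variable, the all-variables
#' mask is returned with a warning.  `fitness_history$best` is the
#' best-so-far RMSECV curve (non-increasing under elitism).
#'
#' @param X Autoscaled matrix.
#' @param y +1/-1 coded response.
#' @param cfg A [ga_config()].
#' @param seed Integer seed for the search.
#' @return Object of class `ga_result`: `best_mask` (variable-space
#'   logical), `best_fitness`, `fitness_history` (data.frame with
#'   `generation`, `best`, `mean`), `generations_run`, `seed`.
#' @export
run_ga <- function(X, y, cfg = ga_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ga_config"))
  X <- as.matrix(X)
  p <- ncol(X)
  g <- as.integer(ceiling(p / cfg$window_width))
  folds <- venetian_blinds(nrow(X), cfg$cv_folds)

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(as.integer(seed))

  cache <- new.env(parent = emptyenv())
  fitness_of <- function(genes) {
    key <- paste0("m", paste(which(genes), collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- ga_fitness(window_expand(genes, cfg$window_width, p), X, y,
                      cfg$n_lv, folds)
    cache[[key]] <- val
    val
  }

  pop <- matrix(stats::runif(cfg$population_size * g) < cfg$init_inclusion_prob,
                nrow = cfg$population_size)
  hist_best <- hist_mean <- numeric(0)
  best_genes <- NULL; best_fit <- Inf; best_key <- Inf; best_nv <- Inf
  run_min <- Inf; stall <- 0L
  gen <- 0L
  while (gen < cfg$max_generations) {
    gen <- gen + 1L
    fits <- apply(pop, 1L, fitness_of)
    nvars <- rowSums(pop)
    # parsimony rule (one-standard-error style): RMSECV values within a
    # 2% relative band are treated as equivalent and ranked by variable
    # count, so the search keeps pruning chance channels once the
    # cross-validation floor is reached instead of drifting at random
    keys <- fitness_band(fits)
    o <- order(keys, nvars, fits)
    improved <- keys[o[1L]] < best_key ||
      (keys[o[1L]] == best_key && nvars[o[1L]] < best_nv)
    if (improved) {
      best_key <- keys[o[1L]]; best_fit <- fits[o[1L]]
      best_nv <- nvars[o[1L]]; best_genes <- pop[o[1L], ]; stall <- 0L
    } else stall <- stall + 1L
    run_min <- min(run_min, fits[is.finite(fits)])
    hist_best <- c(hist_best, run_min)
    hist_mean <- c(hist_mean, mean(fits[is.finite(fits)]))
    if (stall >= cfg$stall_limit) break
    if (gen == cfg$max_generations) break

    elite <- pop[o[seq_len(cfg$elitism)], , drop = FALSE]
    n_child <- cfg$population_size - cfg$elitism
    children <- matrix(FALSE, n_child, g)
    for (i in seq_len(n_child)) {
      pa <- pop[tournament_pick(keys, nvars, fits, cfg$tournament_size), ]
      pb <- pop[tournament_pick(keys, nvars, fits, cfg$tournament_size), ]
      children[i, ] <- crossover_two_point(pa, pb)
    }
    flip <- matrix(stats::runif(n_child * g) < cfg$mutation_rate, n_child, g)
    children <- xor(children, flip)
    pop <- rbind(elite, children)
  }

  best_mask <- window_expand(best_genes, cfg$window_width, p)
  all_fit <- fitness_of(rep(TRUE, g))
  if (!any(best_mask) || best_fit > all_fit) {
    warning("GA-selected mask cross-validates worse than all variables; ",
            "falling back to the full variable set")
    best_mask <- rep(TRUE, p)
    best_fit <- all_fit
  }
  structure(list(best_mask = best_mask, best_fitness = best_fit,
                 fitness_history = data.frame(generation = seq_len(gen),
                                              best = hist_best,
                                              mean = hist_mean),
                 generations_run = gen, seed = as.integer(seed)),
            class = "ga_result")
}

# 2%-wide multiplicative bands on the RMSECV scale; monotone, so exact
# fitness order is preserved across bands while near-ties collapse
fitness_band <- function(fits) {
  k <- numeric(length(fits))
  k[!is.finite(fits)] <- Inf
  ok <- is.finite(fits)
  k[ok] <- floor(log(pmax(fits[ok], 1e-8)) / log(1.02))
  k
}

tournament_pick <- function(keys, nvars, fits, size) {
  cand <- sample.int(length(keys), size, replace = FALSE)
  cand[order(keys[cand], nvars[cand], fits[cand])[1L]]
}

crossover_two_point <- function(a, b) {
  g <- length(a)
  if (g < 2L) return(a)
  cuts <- sort(sample.int(g - 1L, min(2L, g - 1L), replace = FALSE))
  if (length(cuts) == 1L) cuts <- c(cuts, g - 1L)
  mid <- (cuts[1L] + 1L):cuts[2L]
  child <- a
  child[mid] <- b[mid]
  child
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %d/%d variables selected, RMSECV %.4f after %d generations\n",
              sum(x$best_mask), length(x$best_mask), x$best_fitness,
              x$generations_run))
  invisible(x)
}
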