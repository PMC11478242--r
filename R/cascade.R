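CASCADE_NODES <- c("cannabinoid_vs_other", "classical_vs_synthetic",
                   "naphthoylpyrrole_vs_rest", "indole_vs_indazole_azaindole",
                   "naphthyl_head", "fub_tail", "f5_pentyl_tail")

# Per-node definition: which samples train it, how they are labeled, and
# the default model settings (LV counts from the per-node model
# descriptions; GA everywhere except classical-vs-synthetic, where
# variable selection was found to hurt prediction).  The head/tail nodes
# are trained on all synthetic cannabinoids except the
# naphthoylpyrrole-core branch, which terminates at the core node.
node_defs <- function() {
  synth <- function(a) a$is_cannabinoid & !is.na(a$is_classical) & !a$is_classical
  list(
    cannabinoid_vs_other = list(
      positive = "cannabinoid", negative = "other_drug",
      n_lv = 3L, use_ga = TRUE,
      labeller = function(a) ifelse(a$is_cannabinoid, "cannabinoid",
                                    "other_drug")),
    classical_vs_synthetic = list(
      positive = "classical", negative = "synthetic",
      n_lv = 2L, use_ga = FALSE,
      labeller = function(a) ifelse(a$is_cannabinoid & !is.na(a$is_classical),
                                    ifelse(a$is_classical, "classical",
                                           "synthetic"), NA_character_)),
    naphthoylpyrrole_vs_rest = list(
      positive = "naphthoylpyrrole", negative = "other_core",
      n_lv = 3L, use_ga = TRUE,
      labeller = function(a) ifelse(synth(a) & a$core_group != "n/a",
                                    ifelse(a$core_group == "naphthoylpyrrole",
                                           "naphthoylpyrrole", "other_core"),
                                    NA_character_)),
    indole_vs_indazole_azaindole = list(
      positive = "indole", negative = "indazole_azaindole",
      n_lv = 2L, use_ga = TRUE,
      labeller = function(a) ifelse(
        synth(a) & a$core_group %in% c("indole", "indazole", "azaindole"),
        ifelse(a$core_group == "indole", "indole", "indazole_azaindole"),
        NA_character_)),
    naphthyl_head = list(
      positive = "naphthyl", negative = "other_head",
      n_lv = 2L, use_ga = TRUE,
      labeller = function(a) ifelse(synth(a) & !is.na(a$head_is_naphthyl),
                                    ifelse(a$head_is_naphthyl, "naphthyl",
                                           "other_head"), NA_character_)),
    fub_tail = list(
      positive = "fub", negative = "other_tail",
      n_lv = 1L, use_ga = TRUE,
      labeller = function(a) ifelse(synth(a) & !is.na(a$tail_is_fub),
                                    ifelse(a$tail_is_fub, "fub",
                                           "other_tail"), NA_character_)),
    f5_pentyl_tail = list(
      positive = "5f_pentyl", negative = "other_tail",
      n_lv = 2L, use_ga = TRUE,
      labeller = function(a) ifelse(synth(a) & !is.na(a$tail_is_5f_pentyl),
                                    ifelse(a$tail_is_5f_pentyl, "5f_pentyl",
                                           "other_tail"), NA_character_))
  )
}

#' Configuration of the decision cascade
#'
#' Per-node model settings for the seven binary nodes.  Defaults: latent
#' variables 3 (cannabinoid vs other), 2 (classical vs synthetic), 3
#' (naphthoylpyrrole), 2 (indole vs indazole/azaindole), 2 (naphthyl
#' head), 1 (FUB tail), 2 (5F-pentyl tail); GA variable selection on
#' everywhere except the classical-vs-synthetic node.  Override any
#' node's `n_lv`, `use_ga` or `ga` (a [ga_config()]) via `...`, e.g.
#' `cascade_config(fub_tail = list(use_ga = FALSE))`.
#'
#' @param ... Named per-node overrides.
#' @param cv_folds Venetian-blinds splits used for node cross-validation
#'   and GA fitness.
#' @return A named list of class `cascade_config` with one entry per
#'   node: `n_lv`, `use_ga`, `ga`, `positive`, `negative`.
#' @export
cascade_config <- function(..., cv_folds = 10L) {
  defs <- node_defs()
  overrides <- list(...)
  bad <- setdiff(names(overrides), CASCADE_NODES)
  if (length(bad))
    stop("unknown cascade node(s): ", paste(bad, collapse = ", "))
  cfg <- lapply(CASCADE_NODES, function(nm) {
    d <- defs[[nm]]
    node <- list(n_lv = d$n_lv, use_ga = d$use_ga,
                 ga = make_ga_config(n_lv = d$n_lv, cv_folds = cv_folds),
                 positive = d$positive, negative = d$negative)
    ov <- overrides[[nm]]
    if (!is.null(ov)) {
      unknown <- setdiff(names(ov), c("n_lv", "use_ga", "ga"))
      if (length(unknown))
        stop("unknown setting(s) for node ", nm, ": ",
             paste(unknown, collapse = ", "))
      node[names(ov)] <- ov
      node$ga$n_lv <- as.integer(node$n_lv)
    }
    node
  })
  names(cfg) <- CASCADE_NODES
  structure(cfg, cv_folds = as.integer(cv_folds), class = "cascade_config")
}

#' Train the hierarchical classification cascade
#'
#' Fits the seven binary PLS-DA nodes of the decision cascade on a
#' labeled [build_matrix()] spectral matrix.  Each node trains only on
#' the samples its routing can reach (e.g. the core-group nodes see only
#' synthetic cannabinoids), with its own autoscaling, optional GA
#' variable mask and Gaussian decision threshold.  A node with fewer
#' than 4 samples in either class is skipped with a warning; the rest of
#' the cascade remains usable.  Per-node calibration and venetian-blinds
#' cross-validation figures of merit are recorded at training time.
#'
#' @param data A `spectrum_matrix` with full annotations.
#' @param cfg A [cascade_config()].
#' @param seed Integer seed; node `i` runs its GA with seed
#'   `seed * 1000 + i`, so the whole bundle is reproducible from
#'   `(data, cfg, seed)`.
#' @return Object of class `eims_cascade`: per-node classifiers and
#'   metrics, the configuration, seed and training provenance.
#' @seealso [predict.eims_cascade()], [evaluate_bundle()]
#' @export
train_cascade <- function(data, cfg = cascade_config(), seed = 1L) {
  stopifnot(inherits(data, "spectrum_matrix"),
            inherits(cfg, "cascade_config"))
  defs <- node_defs()
  k <- attr(cfg, "cv_folds")
  nodes <- list()
  for (i in seq_along(CASCADE_NODES)) {
    nm <- CASCADE_NODES[i]
    labs <- defs[[nm]]$labeller(data$annotations)
    idx <- which(!is.na(labs))
    npos <- sum(labs[idx] == cfg[[nm]]$positive)
    nneg <- length(idx) - npos
    if (npos < 4L || nneg < 4L) {
      warning("node ", nm, " skipped: needs >= 4 samples per class (",
              npos, " positive, ", nneg, " negative)", call. = FALSE)
      nodes[[nm]] <- list(available = FALSE, n_pos = npos, n_neg = nneg)
      next
    }
    X <- data$X[idx, , drop = FALSE]
    y_lab <- labs[idx]
    clf <- plsda(X, y_lab, positive = cfg[[nm]]$positive,
                 n_lv = cfg[[nm]]$n_lv, use_ga = cfg[[nm]]$use_ga,
                 ga_config = cfg[[nm]]$ga, mz_axis = data$mz_axis,
                 seed = seed * 1000L + i)
    cal_pred <- predict(clf, X)
    cal_cm <- confusion(y_lab, cal_pred$label, cfg[[nm]]$positive)
    cv_cm <- cv_confusion(X, y_lab, cfg[[nm]]$positive, clf$variable_mask,
                          cfg[[nm]]$n_lv, k)
    nodes[[nm]] <- list(available = TRUE, classifier = clf,
                        n_pos = npos, n_neg = nneg,
                        sample_ids = data$sample_ids[idx],
                        calibration = cal_cm, cross_validation = cv_cm)
  }
  structure(list(nodes = nodes, config = cfg, seed = as.integer(seed),
                 mz_axis = data$mz_axis,
                 provenance = list(n_train = nrow(data$X),
                                   p = ncol(data$X),
                                   data_checksum = sprintf("%.10e",
                                                           sum(data$X)))),
            class = "eims_cascade")
}

# Venetian-blinds CV of one node with the variable mask held fixed:
# scaling, PLS fit and threshold are re-estimated inside every fold.
cv_confusion <- function(X, labels, positive, variable_mask, n_lv, k) {
  folds <- venetian_blinds(nrow(X), min(k, nrow(X)))
  Xm <- X[, variable_mask, drop = FALSE]
  y <- ifelse(labels == positive, 1, -1)
  pred <- character(nrow(X))
  for (f in seq_len(folds$k) - 1L) {
    test <- folds$assignments == f
    sc <- autoscale_fit(Xm[!test, , drop = FALSE])
    Ztr <- autoscale_apply(sc, Xm[!test, , drop = FALSE])
    a <- min(n_lv, ncol(Ztr), sum(!test) - 1L)
    fit <- fit_pls(Ztr, y[!test], a)
    thr <- fit_threshold(fit$fitted[y[!test] > 0], fit$fitted[y[!test] < 0])
    sc_te <- predict(fit, autoscale_apply(sc, Xm[test, , drop = FALSE]))
    pred[test] <- ifelse(sc_te >= thr, positive, ".__negative__.")
  }
  neg <- setdiff(unique(labels), positive)
  pred[pred == ".__negative__."] <- neg
  cm <- confusion(labels, pred, positive)
  attr(cm, "pred") <- pred
  cm
}

#' @export
print.eims_cascade <- function(x, ...) {
  cat("<eims_cascade> hierarchical PLS-DA classification system\n")
  for (nm in CASCADE_NODES) {
    nd <- x$nodes[[nm]]
    if (is.null(nd) || !nd$available) {
      cat(sprintf("  %-28s unavailable\n", nm))
    } else {
      cat(sprintf("  %-28s %d LV%s, cal MCC %.4f, CV MCC %.4f (n=%d+%d)\n",
                  nm, nd$classifier$n_lv,
                  if (is.null(nd$classifier$ga_result)) "" else " +GA",
                  mcc(nd$calibration), mcc(nd$cross_validation),
                  nd$n_pos, nd$n_neg))
    }
  }
  invisible(x)
}

#' @export
summary.eims_cascade <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' Classify an unknown spectrum through the cascade
#'
#' Routes a query spectrum through the decision tree: the root node
#' separates cannabinoids from other drugs; cannabinoids are split into
#' classical and synthetic; synthetics into naphthoylpyrrole-core versus
#' the indole/indazole/azaindole branch, where the core node is followed
#' by the naphthyl-head node and the two independent tail nodes (FUB and
#' 5F-pentyl, evaluated as siblings --- a compound may be negative for
#' both).  A negative at the root stops after one node; a classical
#' cannabinoid stops after two; a naphthoylpyrrole core terminates its
#' branch.  If a node on the routing path is unavailable the annotation
#' is marked partial.
#'
#' @param object A trained [train_cascade()] bundle.
#' @param newdata A [mass_spectrum], a raw intensity vector of length
#'   `length(object$mz_axis)`, or a matrix of such rows (each row is
#'   routed independently; a list of results is returned).
#' @param ... Unused.
#' @return For a single spectrum, an object of class `cascade_result`:
#'   `nodes` (data.frame: node, executed, label, score, threshold),
#'   `annotation` (category plus core/head/tail calls) and `partial`.
#' @export
predict.eims_cascade <- function(object, newdata, ...) {
  lo <- min(object$mz_axis); hi <- max(object$mz_axis)
  if (inherits(newdata, "mass_spectrum")) {
    s <- crop_spectrum(normalize_base_peak(newdata, 100), lo, hi)
    if (length(s$mz) == 0L) stop("spectrum has no peaks in the model range")
    v <- bin_to_unit_mass(s, lo, hi)
    return(route_cascade(object, v))
  }
  if (is.matrix(newdata) || inherits(newdata, "spectrum_matrix")) {
    X <- if (inherits(newdata, "spectrum_matrix")) newdata$X else newdata
    return(lapply(seq_len(nrow(X)), function(i) route_cascade(object, X[i, ])))
  }
  route_cascade(object, as.numeric(newdata))
}

route_cascade <- function(bundle, v) {
  stopifnot(length(v) == length(bundle$mz_axis))
  xrow <- matrix(v, nrow = 1L)
  rec <- data.frame(node = CASCADE_NODES, executed = FALSE,
                    label = NA_character_, score = NA_real_,
                    threshold = NA_real_, stringsAsFactors = FALSE)
  partial <- FALSE
  ask <- function(nm) {
    nd <- bundle$nodes[[nm]]
    if (is.null(nd) || !nd$available) return(NULL)
    p <- predict(nd$classifier, xrow)
    i <- match(nm, CASCADE_NODES)
    rec$executed[i] <<- TRUE
    rec$label[i] <<- p$label
    rec$score[i] <<- p$score
    rec$threshold[i] <<- nd$classifier$threshold
    p$label
  }
  annotation <- list(category = NA_character_, core_group = NA_character_,
                     head_is_naphthyl = NA, tail_is_fub = NA,
                     tail_is_5f_pentyl = NA)
  repeat {
    l1 <- ask("cannabinoid_vs_other")
    if (is.null(l1)) { partial <- TRUE; break }
    if (l1 == "other_drug") { annotation$category <- "other drug"; break }
    l2 <- ask("classical_vs_synthetic")
    if (is.null(l2)) { partial <- TRUE; break }
    if (l2 == "classical") {
      annotation$category <- "classical cannabinoid"; break
    }
    annotation$category <- "synthetic cannabinoid"
    l3 <- ask("naphthoylpyrrole_vs_rest")
    if (is.null(l3)) { partial <- TRUE; break }
    if (l3 == "naphthoylpyrrole") {
      annotation$core_group <- "naphthoylpyrrole"; break
    }
    l4 <- ask("indole_vs_indazole_azaindole")
    if (is.null(l4)) partial <- TRUE
    else annotation$core_group <- l4
    l5 <- ask("naphthyl_head")
    if (is.null(l5)) partial <- TRUE
    else annotation$head_is_naphthyl <- l5 == "naphthyl"
    l6 <- ask("fub_tail")
    if (is.null(l6)) partial <- TRUE
    else annotation$tail_is_fub <- l6 == "fub"
    l7 <- ask("f5_pentyl_tail")
    if (is.null(l7)) partial <- TRUE
    else annotation$tail_is_5f_pentyl <- l7 == "5f_pentyl"
    break
  }
  structure(list(nodes = rec, annotation = annotation, partial = partial),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  a <- x$annotation
  cat(sprintf("<cascade_result> %s%s\n", a$category,
              if (x$partial) " (partial)" else ""))
  if (identical(a$category, "synthetic cannabinoid")) {
    cat(sprintf("  core: %s | naphthyl head: %s | FUB tail: %s | 5F-pentyl tail: %s\n",
                a$core_group, a$head_is_naphthyl, a$tail_is_fub,
                a$tail_is_5f_pentyl))
  }
  ex <- x$nodes[x$nodes$executed, ]
  for (i in seq_len(nrow(ex)))
    cat(sprintf("  %-28s -> %-18s score %8.3f (threshold %.3f)\n",
                ex$node[i], ex$label[i], ex$score[i], ex$threshold[i]))
  invisible(x)
}
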