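# Characteristic EI fragment ions per structural moiety.  The m/z values
# are the class-diagnostic fragments of each group (indole core 144,
# indazole/azaindole 145, naphthyl head 127/155, FUB tail 109/252,
# 5F-pentyl-coupled core fragments 232/233, classical cannabinoids
# 41/69/73/91/175/231/260, plus literature fragment sets for the
# non-cannabinoid drug classes).  Mean intensities and presence are NOT
# measured values: they are synthetic choices giving the generator
# realistic relative-abundance structure.
fragment_library <- function() {
  pk <- function(mz, intensity) data.frame(mz = mz, intensity = intensity)
  list(
    core_indole        = pk(c(144, 186, 284), c(100, 55, 35)),
    core_indazole      = pk(c(145, 285), c(100, 35)),
    core_azaindole     = pk(c(145, 285), c(100, 35)),
    core_naphthoylpyrrole = pk(c(127, 155, 219, 246), c(60, 45, 100, 40)),
    core_pentyl_nonF   = list(indole = pk(214, 70), indazole = pk(215, 70),
                              azaindole = pk(215, 70)),
    core_pentyl_5F     = list(indole = pk(232, 70), indazole = pk(233, 70),
                              azaindole = pk(233, 70)),
    head_naphthyl      = pk(c(127, 155), c(80, 65)),
    tail_fub           = pk(c(109, 252), c(100, 60)),
    classical          = pk(c(41, 69, 73, 91, 175, 231, 260),
                            c(70, 80, 40, 55, 45, 100, 60)),
    fentanyl           = pk(c(42, 77, 91, 95, 160, 259),
                            c(60, 50, 70, 45, 80, 100)),
    cathinone          = pk(c(44, 65, 77, 91, 95), c(100, 30, 60, 70, 40)),
    tryptamine         = pk(c(44, 77, 160, 161), c(80, 40, 60, 100)),
    phenethylamine     = pk(c(44, 77, 91, 259), c(90, 55, 60, 100)),
    opioid             = pk(c(42, 44, 70, 77, 91), c(50, 60, 70, 55, 100)),
    generic            = pk(c(43, 55, 57), c(30, 25, 20))
  )
}

#' Built-in simulated compound classes
#'
#' The twelve compound classes the generator emulates: seven cannabinoid
#' classes spanning every cascade node (indole/indazole/azaindole cores,
#' naphthoylpyrrole core, naphthyl and non-naphthyl heads, FUB and
#' 5F-pentyl tails, classical cannabinoids) and five non-cannabinoid
#' drug classes (fentanyl-, cathinone-, tryptamine-, phenethylamine- and
#' non-fentanyl-opioid-like).
#'
#' @return A `data.frame` with one row per class: `class`, `kind`
#'   (`synthetic`/`classical`/`other`), `core`, `head`, `tail`.
#' @export
sim_class_table <- function() {
  data.frame(
    class = c("jwh_like", "indole_5f", "indazole_fub", "indazole_naphthyl",
              "azaindole_5f", "naphthoylpyrrole", "classical",
              "fentanyl_like", "cathinone_like", "tryptamine_like",
              "phenethylamine_like", "opioid_like"),
    kind = c(rep("synthetic", 6L), "classical", rep("other", 5L)),
    core = c("indole", "indole", "indazole", "indazole", "azaindole",
             "naphthoylpyrrole", rep("n/a", 6L)),
    head = c("naphthyl", "other", "other", "naphthyl", "other",
             rep("n/a", 7L)),
    tail = c("pentyl", "5f_pentyl", "fub", "pentyl", "5f_pentyl",
             rep("n/a", 7L)),
    stringsAsFactors = FALSE)
}

#' Compose the fragment profile of one compound class
#'
#' Joins the moiety fragment sets into one peak table, keeping core and
#' tail labels chemically coherent: fluorinated tails couple to the
#' heavier core fragment (232 for indole, 233 for indazole/azaindole)
#' while non-fluorinated pentyl tails give 214/215.  Inconsistent
#' compositions (a classical cannabinoid with a core group, an unknown
#' class kind) are rejected.
#'
#' @param kind `"synthetic"`, `"classical"` or `"other"`.
#' @param core,head,tail Moiety labels as in [sim_class_table()];
#'   `other_class` names the fragment set for `kind = "other"`.
#' @param other_class One of `"fentanyl_like"`, `"cathinone_like"`,
#'   `"tryptamine_like"`, `"phenethylamine_like"`, `"opioid_like"`.
#' @return `data.frame` with `mz` and `intensity` (unique, sorted m/z).
#' @export
compose_profile <- function(kind, core = "n/a", head = "n/a", tail = "n/a",
                            other_class = NULL) {
  lib <- fragment_library()
  if (kind == "classical" && core != "n/a")
    stop("inconsistent profile: a classical cannabinoid has no synthetic ",
         "core group")
  if (kind != "synthetic" && (head != "n/a" || tail != "n/a"))
    stop("inconsistent profile: head/tail groups require a synthetic ",
         "cannabinoid")
  parts <- list(lib$generic)
  if (kind == "classical") {
    parts <- c(parts, list(lib$classical))
  } else if (kind == "synthetic") {
    if (!core %in% c("indole", "indazole", "azaindole", "naphthoylpyrrole"))
      stop("unknown synthetic core: ", core)
    parts <- c(parts, list(lib[[paste0("core_", core)]]))
    if (core != "naphthoylpyrrole") {
      coupling <- if (tail == "5f_pentyl") lib$core_pentyl_5F else lib$core_pentyl_nonF
      parts <- c(parts, list(coupling[[core]]))
    }
    if (head == "naphthyl") parts <- c(parts, list(lib$head_naphthyl))
    if (tail == "fub") parts <- c(parts, list(lib$tail_fub))
  } else if (kind == "other") {
    key <- sub("_like$", "", if (is.null(other_class)) "" else other_class)
    if (!key %in% c("fentanyl", "cathinone", "tryptamine", "phenethylamine",
                    "opioid"))
      stop("unknown drug class: ", other_class)
    parts <- c(parts, list(lib[[key]]))
  } else stop("unknown kind: ", kind)
  prof <- do.call(rbind, parts)
  prof <- prof[order(prof$mz), , drop = FALSE]
  # a fragment contributed twice (e.g. naphthyl 127 on a naphthoylpyrrole
  # core) is kept once at its larger mean
  prof <- do.call(rbind, lapply(split(prof, prof$mz), function(d)
    d[which.max(d$intensity), , drop = FALSE]))
  rownames(prof) <- NULL
  prof
}

#' Simulation configuration
#'
#' Controls the synthetic EI-spectrum generator.  Defaults emulate the
#' scale of the curated EI libraries the cascade is designed for
#' (roughly 430 training and 80 test spectra): 36 training and 8 test
#' compounds per class over the twelve built-in classes,
#' multiplicative log-normal intensity jitter (sigma 0.25), a 5% chance
#' that any characteristic peak other than the class base peak is
#' missing, and 15 uniform noise peaks per spectrum at intensities up to
#' 20% of the base peak.  `jitter_sigma = 0, dropout = 0,
#' n_noise_peaks = 0` gives the noiseless, linearly separable regime.
#'
#' @param n_train,n_test Compounds per class in each split (>= 4).
#' @param jitter_sigma Log-normal sigma of multiplicative intensity noise.
#' @param dropout Per-peak omission probability (< 1).
#' @param n_noise_peaks Random noise peaks per spectrum.
#' @param noise_intensity_max Upper bound of noise-peak intensities
#'   (base peak = 100).
#' @param lo,hi m/z range of generated peaks.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_train = 36L, n_test = 8L, jitter_sigma = 0.25,
                       dropout = 0.05, n_noise_peaks = 15L,
                       noise_intensity_max = 20, lo = 40L, hi = 300L,
                       seed = 1L) {
  stopifnot(jitter_sigma >= 0, dropout >= 0, dropout < 1,
            n_noise_peaks >= 0, noise_intensity_max > 0)
  if (n_train < 4L || n_test < 4L)
    stop("need at least 4 compounds per class in each split")
  structure(list(n_train = as.integer(n_train), n_test = as.integer(n_test),
                 jitter_sigma = jitter_sigma, dropout = dropout,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_intensity_max = noise_intensity_max,
                 lo = as.integer(lo), hi = as.integer(hi),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate one synthetic spectrum with its annotation
#'
#' Draws a spectrum from a compound class's composed fragment profile
#' using the current RNG state: each characteristic peak is present with
#' probability `1 - dropout` (the class base peak is always present),
#' intensities are jittered log-normally, noise peaks are placed at
#' unoccupied m/z positions, and the result is base-peak normalized to
#' 100.  The returned annotation carries ground-truth labels for every
#' cascade node.
#'
#' @param class_row One row of [sim_class_table()] (or a list with the
#'   same fields).
#' @param cfg A [sim_config()].
#' @param compound_id Identifier for the generated compound.
#' @param source Provenance tag.
#' @return List with elements `spectrum` ([mass_spectrum]) and
#'   `annotation` (one-row [class_annotation]).
#' @export
generate_spectrum <- function(class_row, cfg = sim_config(),
                              compound_id = class_row$class,
                              source = "simulated") {
  prof <- compose_profile(class_row$kind, class_row$core, class_row$head,
                          class_row$tail,
                          other_class = if (class_row$kind == "other")
                            class_row$class else NULL)
  keep <- stats::runif(nrow(prof)) >= cfg$dropout
  keep[which.max(prof$intensity)] <- TRUE   # base peak never drops out
  mz <- prof$mz[keep]
  intensity <- prof$intensity[keep]
  if (cfg$jitter_sigma > 0)
    intensity <- intensity * stats::rlnorm(length(intensity), 0,
                                           cfg$jitter_sigma)
  if (cfg$n_noise_peaks > 0L) {
    free <- setdiff(cfg$lo:cfg$hi, prof$mz)
    noise_mz <- sample(free, min(cfg$n_noise_peaks, length(free)))
    mz <- c(mz, noise_mz)
    intensity <- c(intensity,
                   stats::runif(length(noise_mz), 0.5,
                                cfg$noise_intensity_max))
  }
  sp <- mass_spectrum(name = compound_id, mz = mz, intensity = intensity,
                      compound_id = compound_id, source = source)
  sp <- normalize_base_peak(sp, 100)
  synthetic <- class_row$kind == "synthetic"
  pyr <- synthetic && class_row$core == "naphthoylpyrrole"
  ann <- class_annotation(
    compound_id = compound_id,
    is_cannabinoid = class_row$kind %in% c("synthetic", "classical"),
    is_classical = if (class_row$kind == "classical") TRUE
      else if (synthetic) FALSE else NA,
    core_group = if (synthetic) class_row$core else "n/a",
    # head/tail labels only where the cascade routes: the
    # naphthoylpyrrole branch terminates at the core node
    head_is_naphthyl = if (synthetic && !pyr) class_row$head == "naphthyl"
      else NA,
    tail_is_fub = if (synthetic && !pyr) class_row$tail == "fub" else NA,
    tail_is_5f_pentyl = if (synthetic && !pyr) class_row$tail == "5f_pentyl"
      else NA)
  list(spectrum = sp, annotation = ann)
}

#' Generate a full train/test dataset
#'
#' Draws `n_train + n_test` compounds per class with disjoint compound
#' ids across the splits, assembles both splits with [build_matrix()],
#' and guarantees every cascade node sees both of its labels in both
#' splits.  Fully determined by `(cfg, cfg$seed)`.
#'
#' @param cfg A [sim_config()].
#' @param classes Class table (default [sim_class_table()]).
#' @param raw If `TRUE`, return the spectra and annotation tables
#'   themselves (for MSP/CSV export) instead of assembled matrices.
#' @return List with `train` and `test`: [build_matrix()]
#'   `spectrum_matrix` objects, or (with `raw = TRUE`) lists with
#'   `spectra` and `annotations`.
#' @export
generate_dataset <- function(cfg = sim_config(), classes = sim_class_table(),
                             raw = FALSE) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(cfg$seed)
  gen_split <- function(n, tag) {
    spectra <- list(); anns <- list()
    for (ci in seq_len(nrow(classes))) {
      row <- classes[ci, ]
      for (i in seq_len(n)) {
        id <- sprintf("sim_%s_%s_%03d", row$class, tag, i)
        g <- generate_spectrum(row, cfg, compound_id = id, source = tag)
        spectra[[length(spectra) + 1L]] <- g$spectrum
        anns[[length(anns) + 1L]] <- g$annotation
      }
    }
    list(spectra = spectra,
         annotations = validate_annotation(do.call(rbind, anns)))
  }
  train <- gen_split(cfg$n_train, "train")
  test <- gen_split(cfg$n_test, "test")
  if (raw) return(list(train = train, test = test))
  list(train = build_matrix(train$spectra, train$annotations,
                            lo = cfg$lo, hi = cfg$hi),
       test = build_matrix(test$spectra, test$annotations,
                           lo = cfg$lo, hi = cfg$hi))
}
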