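# Shared trained cascade on the small noiseless dataset (GA off: these
# tests exercise training mechanics and routing, not variable selection)
trained_tiny <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- train_cascade(tiny_noiseless()$train, no_ga_config(),
                              seed = 2)
    cache
  }
})

test_that("all seven nodes train and calibrate perfectly on noiseless data", {
  b <- trained_tiny()
  expect_s3_class(b, "eims_cascade")
  for (nm in NODE_NAMES) {
    nd <- b$nodes[[nm]]
    expect_true(nd$available, info = nm)
    expect_equal(mcc(nd$calibration), 1, info = nm)
    expect_equal(mcc(nd$cross_validation), 1, info = nm)
  }
})

test_that("cascade configuration validates node names and settings", {
  expect_error(cascade_config(not_a_node = list(n_lv = 2)), "unknown cascade")
  expect_error(cascade_config(fub_tail = list(bogus = 1)), "bogus")
  cfg <- cascade_config(fub_tail = list(n_lv = 3))
  expect_equal(cfg$fub_tail$n_lv, 3)
  expect_equal(cfg$cannabinoid_vs_other$n_lv, 3L)
  expect_false(cfg$classical_vs_synthetic$use_ga)
})

test_that("a JWH-like spectrum routes through the full synthetic branch", {
  b <- trained_tiny()
  ds <- tiny_noiseless()
  id <- grep("jwh_like_test", ds$test$sample_ids)[1]
  r <- predict(b, ds$test$X[id, ])
  expect_s3_class(r, "cascade_result")
  expect_equal(r$annotation$category, "synthetic cannabinoid")
  expect_equal(r$annotation$core_group, "indole")
  expect_true(r$annotation$head_is_naphthyl)
  expect_false(r$annotation$tail_is_fub)
  expect_false(r$annotation$tail_is_5f_pentyl)
  # the full indole branch runs every node
  expect_setequal(r$nodes$node[r$nodes$executed], NODE_NAMES)
})

test_that("classical cannabinoids stop after two nodes", {
  b <- trained_tiny()
  ds <- tiny_noiseless()
  id <- grep("classical_test", ds$test$sample_ids)[1]
  r <- predict(b, ds$test$X[id, ])
  expect_equal(r$annotation$category, "classical cannabinoid")
  expect_equal(sum(r$nodes$executed), 2L)
  expect_true(is.na(r$annotation$core_group))
})

test_that("non-cannabinoids are rejected at the root with one executed node", {
  b <- trained_tiny()
  ds <- tiny_noiseless()
  id <- grep("fentanyl_like_test", ds$test$sample_ids)[1]
  r <- predict(b, ds$test$X[id, ])
  expect_equal(r$annotation$category, "other drug")
  expect_equal(sum(r$nodes$executed), 1L)
})

test_that("a naphthoylpyrrole core terminates its branch at the core node", {
  b <- trained_tiny()
  ds <- tiny_noiseless()
  id <- grep("naphthoylpyrrole_test", ds$test$sample_ids)[1]
  r <- predict(b, ds$test$X[id, ])
  expect_equal(r$annotation$core_group, "naphthoylpyrrole")
  expect_false(r$nodes$executed[r$nodes$node == "naphthyl_head"])
  expect_false(r$nodes$executed[r$nodes$node == "fub_tail"])
  expect_equal(sum(r$nodes$executed), 3L)
})

test_that("mass_spectrum input routes like its binned vector", {
  b <- trained_tiny()
  ds <- generate_dataset(sim_config(n_train = 6L, n_test = 4L,
                                    jitter_sigma = 0, dropout = 0,
                                    n_noise_peaks = 0L, seed = 11L),
                         raw = TRUE)
  s <- ds$test$spectra[[1]]
  r1 <- predict(b, s)
  v <- bin_to_unit_mass(crop_spectrum(normalize_base_peak(s)))
  r2 <- predict(b, v)
  expect_identical(r1$annotation, r2$annotation)
})

test_that("a dataset without FUB examples trains 6 nodes and flags partial results", {
  classes <- sim_class_table()
  classes <- classes[classes$class != "indazole_fub", ]
  ds <- generate_dataset(sim_config(n_train = 6L, n_test = 4L,
                                    jitter_sigma = 0, dropout = 0,
                                    n_noise_peaks = 0L, seed = 23L), classes)
  expect_warning(b <- train_cascade(ds$train, no_ga_config(), seed = 2),
                 "fub_tail skipped")
  expect_false(b$nodes$fub_tail$available)
  expect_equal(sum(vapply(b$nodes, function(n) isTRUE(n$available), TRUE)),
               6L)
  id <- grep("jwh_like_test", ds$test$sample_ids)[1]
  r <- predict(b, ds$test$X[id, ])
  expect_true(r$partial)
  expect_true(is.na(r$annotation$tail_is_fub))
  expect_equal(r$annotation$category, "synthetic cannabinoid")
})

test_that("training is deterministic: identical bundles byte for byte", {
  ds <- tiny_noiseless()
  cfg <- cascade_config(
    cannabinoid_vs_other = list(ga = ga_config(max_generations = 4,
                                               n_lv = 3, stall_limit = 2)),
    naphthoylpyrrole_vs_rest = list(use_ga = FALSE),
    indole_vs_indazole_azaindole = list(use_ga = FALSE),
    naphthyl_head = list(use_ga = FALSE),
    fub_tail = list(use_ga = FALSE),
    f5_pentyl_tail = list(use_ga = FALSE))
  b1 <- train_cascade(ds$train, cfg, seed = 5)
  b2 <- train_cascade(ds$train, cfg, seed = 5)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  save_bundle(b1, f1)
  save_bundle(b2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("bundles survive a save/load round trip with identical predictions", {
  b <- trained_tiny()
  ds <- tiny_noiseless()
  path <- withr::local_tempfile(fileext = ".json")
  save_bundle(b, path)
  b2 <- load_bundle(path)
  r1 <- predict(b, ds$test$X[5, ])
  r2 <- predict(b2, ds$test$X[5, ])
  expect_equal(r1$nodes$score, r2$nodes$score, tolerance = 1e-12)
  expect_identical(r1$annotation, r2$annotation)
})

test_that("the merit table has the nodes-by-three layout with perfect rows", {
  b <- trained_tiny()
  ds <- tiny_noiseless()
  tab <- evaluate_bundle(b, ds$train, ds$test)
  expect_equal(nrow(tab), length(NODE_NAMES) * 3L)
  expect_setequal(unique(tab$set),
                  c("calibration", "cross-validation", "external validation"))
  for (col in c("accuracy", "TPR", "TNR", "F1", "MCC"))
    expect_true(all(tab[[col]] == 1), info = col)
  expect_true(all(tab$misclassified == ""))
  # stored-metrics variant (no calibration matrix supplied)
  tab2 <- evaluate_bundle(b, test = ds$test)
  expect_equal(nrow(tab2), 21L)
  expect_true(all(tab2$MCC == 1))
})
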