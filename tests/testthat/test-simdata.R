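test_that("composed profiles carry the class-diagnostic fragments", {
  indole <- compose_profile("synthetic", core = "indole", head = "other",
                            tail = "pentyl")
  expect_true(all(c(144, 186, 214) %in% indole$mz))
  indole_5f <- compose_profile("synthetic", core = "indole", head = "other",
                               tail = "5f_pentyl")
  expect_true(232 %in% indole_5f$mz)       # fluorinated core-tail fragment
  expect_false(214 %in% indole_5f$mz)
  aza_5f <- compose_profile("synthetic", core = "azaindole", head = "other",
                            tail = "5f_pentyl")
  expect_true(233 %in% aza_5f$mz)
  fub <- compose_profile("synthetic", core = "indazole", head = "other",
                         tail = "fub")
  expect_true(all(c(109, 252) %in% fub$mz))
  naph <- compose_profile("synthetic", core = "indole", head = "naphthyl",
                          tail = "pentyl")
  expect_true(all(c(127, 155) %in% naph$mz))
  classical <- compose_profile("classical")
  expect_true(all(c(41, 69, 73, 91, 175, 231, 260) %in% classical$mz))
})

test_that("inconsistent profile compositions are rejected", {
  expect_error(compose_profile("classical", core = "indole"), "inconsistent")
  expect_error(compose_profile("other", head = "naphthyl",
                               other_class = "fentanyl_like"),
               "inconsistent")
  expect_error(compose_profile("other", other_class = "benzo_like"),
               "unknown drug class")
  expect_error(compose_profile("synthetic", core = "pyridine"),
               "unknown synthetic core")
})

test_that("generated spectra contain their diagnostic peaks and repeat under a seed", {
  row <- sim_class_table()[1, ]   # indole core, naphthyl head
  cfg <- sim_config(jitter_sigma = 0, dropout = 0, n_noise_peaks = 0,
                    seed = 1)
  set.seed(91)
  g <- generate_spectrum(row, cfg, compound_id = "a")
  expect_true(144 %in% g$spectrum$mz)
  expect_true(g$annotation$is_cannabinoid)
  expect_equal(g$annotation$core_group, "indole")
  set.seed(91)
  g2 <- generate_spectrum(row, cfg, compound_id = "a")
  expect_identical(g, g2)
})

test_that("noise peaks never collide with the composed profile", {
  row <- sim_class_table()[3, ]
  prof <- compose_profile(row$kind, row$core, row$head, row$tail)
  cfg <- sim_config(seed = 1)
  set.seed(92)
  for (i in 1:1000) {
    g <- generate_spectrum(row, cfg, compound_id = "x")
    pos <- round(g$spectrum$mz)
    # noise lands only on unoccupied channels: no stacking anywhere
    expect_false(any(duplicated(pos)))
    expect_lte(length(pos), nrow(prof) + cfg$n_noise_peaks)
    # noise peaks stay below the characteristic-peak intensity scale
    noise_int <- g$spectrum$intensity[!pos %in% prof$mz]
    if (length(noise_int)) expect_lte(max(noise_int), 100)
  }
})

test_that("generated datasets populate every cascade node in both splits", {
  ds <- tiny_noiseless()
  defs <- asNamespace("eimsCascade")$node_defs()
  for (nm in NODE_NAMES) {
    for (split in list(ds$train, ds$test)) {
      labs <- defs[[nm]]$labeller(split$annotations)
      expect_equal(length(unique(stats::na.omit(labs))), 2L,
                   info = paste(nm))
    }
  }
})

test_that("train and test compound ids are disjoint and counts match", {
  cfg <- sim_config(n_train = 10L, n_test = 4L, seed = 13)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$train$X), 120L)   # 10 per class x 12 classes
  expect_equal(nrow(ds$test$X), 48L)
  expect_length(intersect(ds$train$sample_ids, ds$test$sample_ids), 0L)
  expect_error(sim_config(n_train = 3), "at least 4")
})

test_that("dataset generation is fully determined by its config and seed", {
  cfg <- sim_config(n_train = 4L, n_test = 4L, seed = 17)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$train$X, d2$train$X)
  expect_identical(d1$test$X, d2$test$X)
})

test_that("generated peaks survive the normalize-crop-bin pipeline unchanged", {
  ds <- generate_dataset(sim_config(n_train = 4L, n_test = 4L, seed = 19),
                         raw = TRUE)
  s <- ds$train$spectra[[1]]
  binned <- bin_to_unit_mass(crop_spectrum(normalize_base_peak(s)))
  expect_setequal(as.integer(names(binned)[binned > 0]), round(s$mz))
})
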