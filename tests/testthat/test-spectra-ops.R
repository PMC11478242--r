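test_that("base-peak normalization rescales linearly", {
  s <- mass_spectrum("x", c(116, 144), c(250, 500))
  n <- normalize_base_peak(s, 100)
  expect_equal(n$intensity, c(50, 100))
  # already normalized -> unchanged
  expect_equal(normalize_base_peak(n, 100)$intensity, n$intensity)
  expect_error(normalize_base_peak(s, -1))
})

test_that("normalization preserves intensity ratios", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_spectrum()
    n <- normalize_base_peak(s)
    expect_equal(n$intensity / n$intensity[1],
                 s$intensity / s$intensity[1], tolerance = 1e-12)
  }
})

test_that("cropping keeps the inclusive 40-300 window and is idempotent", {
  s <- mass_spectrum("x", c(39, 40, 300, 301), c(1, 2, 3, 4))
  cs <- crop_spectrum(s)
  expect_equal(cs$mz, c(40, 300))
  inside <- mass_spectrum("x", c(50, 200), c(1, 2))
  expect_equal(crop_spectrum(inside)$mz, inside$mz)
  set.seed(8)
  for (i in 1:20) {
    s <- random_spectrum()
    once <- crop_spectrum(s)
    expect_identical(crop_spectrum(once), once)
  }
})

test_that("unit-mass binning sums peaks by rounded m/z", {
  s <- mass_spectrum("x", 144.0, 999)
  v <- bin_to_unit_mass(s)
  expect_length(v, 261L)
  expect_equal(unname(v[105]), 999)  # 144 - 40 + 1
  expect_equal(sum(v > 0), 1L)
  s2 <- mass_spectrum("x", c(143.6, 144.4), c(5, 10))
  v2 <- bin_to_unit_mass(s2)
  expect_equal(unname(v2["144"]), 15)
  # binned total equals the retained peak total
  set.seed(9)
  for (i in 1:10) {
    s <- crop_spectrum(random_spectrum())
    expect_equal(sum(bin_to_unit_mass(s)), sum(s$intensity))
  }
})

test_that("build_matrix assembles aligned rows and rejects bad inputs", {
  set.seed(10)
  spectra <- lapply(1:3, function(i) {
    s <- random_spectrum()
    s$name <- s$compound_id <- paste0("c", i)
    s
  })
  ann <- class_annotation(paste0("c", 1:3), is_cannabinoid = c(TRUE, FALSE, TRUE))
  sm <- build_matrix(spectra, ann)
  expect_equal(dim(sm$X), c(3L, 261L))
  expect_equal(sm$sample_ids, paste0("c", 1:3))
  expect_equal(sm$annotations$compound_id, paste0("c", 1:3))
  # missing annotation names the compound
  expect_error(build_matrix(spectra, ann[1:2, ]), "c3")
  # duplicate id rejected
  expect_error(build_matrix(c(spectra, spectra[1]),
                            rbind(ann, ann[1, ])), "duplicate")
})

test_that("permuting input spectra permutes matrix rows identically", {
  set.seed(12)
  spectra <- lapply(1:5, function(i) {
    s <- random_spectrum()
    s$name <- s$compound_id <- paste0("c", i)
    s
  })
  ann <- class_annotation(paste0("c", 1:5), is_cannabinoid = TRUE)
  sm1 <- build_matrix(spectra, ann)
  perm <- c(3, 1, 5, 2, 4)
  sm2 <- build_matrix(spectra[perm], ann)
  expect_identical(sm2$X, sm1$X[perm, ])
  expect_identical(sm2$annotations$compound_id,
                   sm1$annotations$compound_id[perm])
})

test_that("normalize-crop-bin pipeline is bitwise deterministic", {
  set.seed(13)
  s <- random_spectrum()
  v1 <- bin_to_unit_mass(crop_spectrum(normalize_base_peak(s)))
  v2 <- bin_to_unit_mass(crop_spectrum(normalize_base_peak(s)))
  expect_identical(v1, v2)
})

test_that("annotation validation rejects incoherent label sets", {
  expect_error(class_annotation("a", FALSE, is_classical = TRUE),
               "non-cannabinoid")
  expect_error(class_annotation("a", TRUE, is_classical = TRUE,
                                core_group = "indole"), "synthetic")
  expect_error(class_annotation("a", TRUE, is_classical = FALSE,
                                core_group = "pyridine"), "core_group")
  ok <- class_annotation("a", TRUE, is_classical = FALSE,
                         core_group = "indole", head_is_naphthyl = TRUE,
                         tail_is_fub = FALSE, tail_is_5f_pentyl = FALSE)
  expect_s3_class(ok, "class_annotation")
})

test_that("annotation tables round-trip through CSV", {
  ann <- rbind(
    class_annotation("a", TRUE, is_classical = FALSE, core_group = "indole",
                     head_is_naphthyl = TRUE, tail_is_fub = FALSE,
                     tail_is_5f_pentyl = FALSE),
    class_annotation("b", FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_equal(as.data.frame(back), as.data.frame(ann))
})
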