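small_study <- function() {
  v <- function(seed) {
    set.seed(seed)
    spect_volume(array(runif(16^3, 0, 50), c(16, 16, 16)))
  }
  p <- function(seed) {
    set.seed(seed)
    planar_image(matrix(runif(32^2, 0, 20), 32, 32))
  }
  labs <- array(0L, c(16, 16, 16))
  labs[2:5, 2:5, 2:5] <- 1L; labs[10:12, 10:12, 10:12] <- 2L
  labs[7, 7, 7] <- 3L
  mibg_study(v(1), v(2), p(3), p(4),
             acquisition_meta(111, 61.1, 0.3, 3.3),
             truth = list(early = organ_labelmap(labs),
                          late = organ_labelmap(labs)))
}

test_that("constructors enforce the domain invariants", {
  expect_error(spect_volume(array(-1, c(4, 4, 4))), "counts")
  expect_error(spect_volume(array(1, c(4, 4)), ), "3-D")
  expect_error(spect_volume(array(1, c(4, 4, 4)), spacing_mm = c(6.6, 0, 6.6)),
               "spacing")
  expect_error(planar_image(matrix(-0.1, 4, 4)), "counts")
  expect_error(acquisition_meta(0, 60, 0.3, 3.3), "injected_dose_mbq")
  expect_error(acquisition_meta(111, -5, 0.3, 3.3), "body_weight_kg")
  expect_error(acquisition_meta(111, 60, 3.3, 0.3), "t_late_h")
  expect_error(organ_labelmap(array(7L, c(4, 4, 4))), "labels")
  bad_late <- spect_volume(array(1, c(8, 8, 8)))
  ok_early <- spect_volume(array(1, c(16, 16, 16)))
  pl <- planar_image(matrix(1, 8, 8))
  expect_error(mibg_study(ok_early, bad_late, pl, pl,
                          acquisition_meta(111, 60, 0.3, 3.3)),
               "share shape")
})

test_that("a study round-trips through its directory layout field-wise", {
  s <- small_study()
  dir <- withr::local_tempdir()
  save_study(s, dir)
  s2 <- load_study(dir)
  expect_equal(s2$early$counts, s$early$counts, tolerance = 1e-6)
  expect_equal(s2$late$counts, s$late$counts, tolerance = 1e-6)
  expect_equal(s2$planar_early$counts, s$planar_early$counts,
               tolerance = 1e-6)
  expect_equal(s2$planar_late$counts, s$planar_late$counts, tolerance = 1e-6)
  expect_equal(s2$meta, s$meta)
  expect_identical(s2$truth$early$labels, s$truth$early$labels)
  expect_equal(s2$early$spacing_mm, s$early$spacing_mm, tolerance = 1e-6)
})

test_that("loading reports missing files and invalid sidecars by name", {
  s <- small_study()
  dir <- withr::local_tempdir()
  save_study(s, dir)
  file.remove(file.path(dir, "late_spect.nii.gz"))
  expect_error(load_study(dir), "late_spect")
  save_study(s, dir)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  meta$t_late_h <- meta$t_early_h - 1
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  expect_error(load_study(dir), "t_late_h")
})

test_that("label maps round-trip losslessly with their spacing", {
  labs <- array(sample(0:3, 12^3, replace = TRUE), c(12, 12, 12))
  m <- organ_labelmap(labs, spacing_mm = c(6.6, 6.6, 6.6))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  save_labelmap(m, path)
  m2 <- load_labelmap(path)
  expect_identical(m2$labels, m$labels)
  expect_equal(m2$spacing_mm, m$spacing_mm, tolerance = 1e-6)
  expect_identical(as.vector(table(m2$labels)), as.vector(table(m$labels)))
  # all-background map
  m0 <- organ_labelmap(array(0L, c(6, 6, 6)))
  save_labelmap(m0, path)
  expect_identical(load_labelmap(path)$labels, m0$labels)
})

test_that("a phantom-generated directory loads back as a valid 64-cube study", {
  ph <- noiseless_phantom()
  dir <- withr::local_tempdir()
  save_study(ph$study, dir)
  s2 <- load_study(dir)
  expect_identical(dim(s2$early$counts), c(64L, 64L, 64L))
  expect_identical(dim(s2$planar_early$counts), c(256L, 256L))
  expect_false(is.null(s2$truth))
})
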