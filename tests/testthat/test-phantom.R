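test_that("phantom parameters are validated", {
  expect_error(phantom_params(uptake_heart = -1), "uptake")
  expect_error(phantom_params(washout_fraction_heart = 1.2), "washout")
  expect_error(phantom_params(heart_outer_radius_mm = 0), "radii")
  expect_error(phantom_params(heart_center_mm = c(600, 240, 260)), "fit inside")
})

test_that("the no-change limit reproduces the early frame", {
  p <- phantom_params(poisson_noise = FALSE, washout_fraction_heart = 0,
                      washout_fraction_background = 0,
                      t_early_h = 1, t_late_h = 1 + 1e-9)
  ph <- generate_phantom(p)
  expect_equal(ph$study$late$counts, ph$study$early$counts,
               tolerance = 1e-7)
})

test_that("an unblurred solid heart carries exactly its uptake", {
  p <- phantom_params(poisson_noise = FALSE, blur_fwhm_mm = 0,
                      wall_thickness_mm = 45, uptake_heart = 100,
                      uptake_mediastinum = 10)
  ph <- generate_phantom(p)
  heart <- ph$truth$labelmap_early$labels == ORGAN_LABELS[["heart"]]
  expect_equal(mean(ph$study$early$counts[heart]), 100, tolerance = 1e-6)
})

test_that("mass balance holds under blur alone", {
  ph <- noiseless_phantom()
  uptake <- mibgquant:::rasterize_phantom(ph$truth$params)$uptake
  expect_equal(sum(ph$study$early$counts), sum(uptake),
               tolerance = 1e-6)
})

test_that("the late frame reflects washout times physical decay", {
  p <- phantom_params(poisson_noise = FALSE, blur_fwhm_mm = 0,
                      wall_thickness_mm = 45)
  ph <- generate_phantom(p)
  heart <- ph$truth$labelmap_early$labels == ORGAN_LABELS[["heart"]]
  dcf <- 0.5^((p$t_late_h - p$t_early_h) / 13)
  expect_equal(mean(ph$study$late$counts[heart]),
               mean(ph$study$early$counts[heart]) *
                 (1 - p$washout_fraction_heart) * dcf,
               tolerance = 1e-9)
})

test_that("the generator is a pure function of its seed", {
  p1 <- generate_phantom(phantom_params(seed = 4))
  p2 <- generate_phantom(phantom_params(seed = 4))
  p3 <- generate_phantom(phantom_params(seed = 5))
  expect_identical(p1$study$early$counts, p2$study$early$counts)
  expect_identical(p1$study$planar_late$counts, p2$study$planar_late$counts)
  expect_false(identical(p1$study$early$counts, p3$study$early$counts))
})

test_that("anterior projection conserves counts and geometry", {
  # uniform volume: interior planar pixels carry the full ray sum, rescaled
  # by the pixel-area ratio
  vol <- spect_volume(array(3, c(64, 64, 64)))
  pl <- project_anterior(vol)
  scale <- (2.4 / 6.6)^2
  expect_equal(pl$counts[128, 128], 64 * 3 * scale, tolerance = 1e-6)
  expect_equal(sum(pl$counts), sum(vol$counts), tolerance = 0.01 * sum(vol$counts))
  # single impulse lands at the projected world position
  arr <- array(0, c(64, 64, 64)); arr[20, 31, 40] <- 100
  vol1 <- spect_volume(arr)
  pl1 <- project_anterior(vol1)
  expect_equal(sum(pl1$counts), 100, tolerance = 1)
  rc <- world_to_planar(c((20 - 0.5) * 6.6, 0, (40 - 0.5) * 6.6), vol1, pl1)
  pk <- which(pl1$counts == max(pl1$counts), arr.ind = TRUE)[1, ]
  expect_lt(max(abs(pk - rc)), 2.5)
})

test_that("projection preserves the uptake ordering of heart over mediastinum", {
  ph <- noiseless_phantom()
  q <- planar_quantify(ph$study, planar_heart_seed(ph))
  expect_gt(q$early$raw_h, q$early$raw_m)
})

test_that("cohorts are seed-reproducible and respect the uptake mix", {
  expect_error(generate_cohort(0), "n")
  expect_error(generate_cohort(5, mix = 1.5), "mix")
  c1 <- generate_cohort(4, mix = 0.5, seed = 2)
  c2 <- generate_cohort(4, mix = 0.5, seed = 2)
  expect_identical(c1[[3]]$study$early$counts, c2[[3]]$study$early$counts)
  expect_identical(vapply(c1, function(x) x$truth$params$reduced, logical(1)),
                   vapply(c2, function(x) x$truth$params$reduced, logical(1)))
  expect_equal(sum(vapply(c1, function(x) x$truth$params$reduced,
                          logical(1))), 2)
})

test_that("a reduced-uptake-free cohort renders with HMR at or above 1.5", {
  cohort <- generate_cohort(10, mix = 0, seed = 3, poisson_noise = FALSE)
  hmrs <- vapply(cohort, function(ph)
    planar_quantify(ph$study, planar_heart_seed(ph))$early$hmr, numeric(1))
  expect_true(all(hmrs >= 1.5))
})
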