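test_that("the binary union keeps lungs and liver only", {
  labs <- array(0L, c(10, 10, 10))
  labs[1:5, 1:5, 1] <- 1L        # 25 lungs
  labs[6:10, 6:10, 1] <- 2L      # 25 liver
  labs[1:2, 8:9, 5] <- 3L        # heart
  m <- organ_labelmap(labs)
  u <- to_binary_union(m)
  expect_equal(sum(u), 50)
  expect_false(any(u[labs == 3L]))
  expect_false(any(to_binary_union(organ_labelmap(array(0L, c(4, 4, 4))))))
})

test_that("resampling through the identity and inverse transforms round-trips", {
  ph <- noiseless_phantom()
  vol <- ph$study$early
  id <- rigid_transform(center_mm = dim(vol$counts) * vol$spacing_mm / 2)
  expect_equal(resample(vol, id)$counts, vol$counts, tolerance = 1e-6)
  # grid-aligned translations round-trip exactly
  t2v <- rigid_transform(c(13.2, 0, 0), center_mm = id$center_mm)
  back_t <- resample(resample(vol, t2v), rigid_inverse(t2v))
  expect_equal(back_t$counts, vol$counts, tolerance = 1e-9)
  # general motion: double interpolation loses little on an adequately
  # sampled volume (here four voxels per blur FWHM)
  smooth <- generate_phantom(phantom_params(poisson_noise = FALSE,
                                            blur_fwhm_mm = 26.4))$study$early
  t <- rigid_transform(c(5, -3, 7), c(0.03, -0.02, 0.05),
                       dim(smooth$counts) * smooth$spacing_mm / 2)
  back <- resample(resample(smooth, t), rigid_inverse(t))
  expect_lt(sum(abs(back$counts - smooth$counts)), 0.02 * sum(smooth$counts))
})

test_that("nearest-neighbour shifts invert exactly away from the border", {
  mask <- array(0, c(16, 16, 16)); mask[6:10, 6:10, 6:10] <- 1
  sp <- c(6.6, 6.6, 6.6)
  t <- rigid_transform(c(6.6, 0, 0), center_mm = 16 * sp / 2)
  fwd <- resample(mask, t, "nearest", sp)
  back <- resample(fwd, rigid_inverse(t), "nearest", sp)
  expect_equal(back[2:15, , ], mask[2:15, , ])
})

test_that("linear resampling of a binary mask stays within [0, 1]", {
  mask <- array(0, c(12, 12, 12)); mask[4:8, 4:8, 4:8] <- 1
  t <- rigid_transform(c(3.1, -2.2, 1.7), c(0.02, 0, -0.03),
                       center_mm = 12 * 6.6 / 2 * c(1, 1, 1))
  out <- resample(mask, t, "linear", c(6.6, 6.6, 6.6))
  expect_gte(min(out), 0)
  expect_lte(max(out), 1 + 1e-12)
  expect_true(any(out > 0 & out < 1))  # fractional edges exist
})

test_that("self-registration stays at the identity", {
  ph <- noiseless_phantom()
  u <- to_binary_union(ph$truth$labelmap_early)
  reg <- register_masks(u, u, n_iter = 50L)
  expect_lt(max(abs(reg$transform$translation_mm)), 0.1)
  expect_lt(max(abs(reg$transform$rotation_rad)), 0.005)
})

test_that("registration recovers known shifts and rotations", {
  p <- phantom_params(poisson_noise = FALSE,
                      intershift_translation_mm = c(13.2, 0, 0))
  ph <- generate_phantom(p)
  reg <- register_masks(to_binary_union(ph$truth$labelmap_early),
                        to_binary_union(ph$truth$labelmap_late),
                        n_iter = 120L)
  expect_lt(max(abs(reg$transform$translation_mm - c(13.2, 0, 0))), 3.3)
  expect_lte(reg$metric, reg$metric_history[1])  # metric non-increase

  p2 <- phantom_params(poisson_noise = FALSE,
                       intershift_rotation_rad = c(0, 0, 5 * pi / 180))
  ph2 <- generate_phantom(p2)
  reg2 <- register_masks(to_binary_union(ph2$truth$labelmap_early),
                         to_binary_union(ph2$truth$labelmap_late),
                         n_iter = 120L)
  expect_lt(abs(reg2$transform$rotation_rad[3] - 5 * pi / 180), pi / 180)
  expect_lte(reg2$metric, reg2$metric_history[1])
})

test_that("empty masks are rejected", {
  z <- array(0, c(8, 8, 8)); o <- z; o[3:5, 3:5, 3:5] <- 1
  expect_error(register_masks(z, o), "empty")
  expect_error(register_masks(o, z), "empty")
})
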