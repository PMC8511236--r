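test_that("decay correction follows the 13-hour half-life", {
  expect_equal(round(decay_correction_factor(3), 2), 0.85)
  expect_identical(decay_correction_factor(0), 1)
  expect_equal(decay_correction_factor(13), 0.5)
  expect_error(decay_correction_factor(-1), "non-negative")
  # strictly decreasing and multiplicative in the interval
  dt <- seq(0, 24, by = 0.5)
  expect_true(all(diff(decay_correction_factor(dt)) < 0))
  expect_equal(decay_correction_factor(7.3),
               decay_correction_factor(4.1) * decay_correction_factor(3.2))
})

test_that("body contour detection measures widths row by row", {
  img <- planar_image(matrix(0, 64, 128))
  img$counts[10:50, 15:114] <- 100
  ct <- detect_body_contour(img, 0.1)
  expect_true(all(ct$width[10:50] == 100))
  expect_true(all(is.na(ct$width[1:9])))
  expect_equal(ct$midline[20], (15 + 114) / 2)
  expect_error(detect_body_contour(planar_image(matrix(0, 8, 8))),
               "all-zero")
})

test_that("the mediastinal ROI takes 10% of body width and 30% of height", {
  img <- planar_image(matrix(0, 220, 256))
  img$counts[11:210, 29:228] <- 50  # body width 200
  ct <- detect_body_contour(img, 0.1)
  roi <- place_mediastinal_roi(img, ct, mediastinum_rows = 41:140)
  expect_equal(roi$right - roi$left + 1L, 20L)
  expect_equal(roi$bottom - roi$top + 1L, 30L)
  expect_equal(roi$top, 41L)
  expect_equal(round((roi$left + roi$right) / 2), 128)
  # width rounding to zero is a placement error
  img2 <- planar_image(matrix(0, 40, 40))
  img2$counts[5:35, 18:21] <- 5  # body width 4 -> 10% rounds to 0
  ct2 <- detect_body_contour(img2, 0.1)
  expect_error(place_mediastinal_roi(img2, ct2, 10:29), "degenerate")
})

test_that("the heart ROI snaps to the local count-weighted centroid", {
  img <- planar_image(matrix(0, 128, 128))
  rows <- rep(1:128, times = 128); cols <- rep(1:128, each = 128)
  blob <- 1000 * exp(-((rows - 70)^2 + (cols - 55)^2) / (2 * 4^2))
  img$counts[] <- blob
  roi1 <- place_heart_roi(img, c(70, 55), radius_px = 12)
  expect_lt(sqrt(sum((roi1$center - c(70, 55))^2)), 1)
  roi2 <- place_heart_roi(img, c(75, 51), radius_px = 12)
  expect_equal(roi2$center, roi1$center, tolerance = 0.5)
  img$counts[1:12, 1:12] <- 0
  expect_error(place_heart_roi(img, c(5, 5), radius_px = 3, search_px = 2),
               "no counts")
})

test_that("ROI means average the pixels whose centres fall inside", {
  u <- planar_image(matrix(7, 16, 16))
  expect_equal(roi_mean_counts(u, roi_rect(3, 6, 3, 6, u)), 7)
  expect_equal(roi_mean_counts(u, roi_circle(c(8, 8), 3.2, u)), 7)
  m <- planar_image(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(roi_mean_counts(m, roi_rect(1, 2, 1, 2, m)), 2.5)
  img <- planar_image(matrix(1:25, 5, 5) * 1.0)
  expect_equal(roi_mean_counts(img, roi_circle(c(3, 4), 0.5, img)),
               img$counts[3, 4])
})

test_that("heart metrics follow the normalisation formulas", {
  meta <- acquisition_meta(111, 55.5, 0.3, 3.3)  # dose/BW = 2
  hm <- heart_metrics(100, 20, 1, meta)
  expect_equal(hm$h_bc, 40)
  expect_equal(hm$h, 50)
  expect_equal(hm$hmr, 5)
  hm2 <- heart_metrics(20, 20, 1, acquisition_meta(60, 60, 0.3, 3.3))
  expect_equal(hm2$h_bc, 0)
  expect_equal(hm2$hmr, 1)
  hm3 <- heart_metrics(100, 20, 0.85, meta)
  expect_equal(hm3$h_bc, (80 / 0.85) / 2, tolerance = 1e-12)
  hm4 <- heart_metrics(10, 0, 1, meta)
  expect_false(hm4$hmr_defined)
  expect_true(is.na(hm4$hmr))
})

test_that("washout rates match their printed formulas", {
  wr0 <- washout_rates(80, 15, 80, 15, 1)
  expect_equal(wr0$wr_bc, 0); expect_equal(wr0$wr_nc, 0)
  expect_equal(wr0$wr_hmr, 0)
  wr <- washout_rates(100, 20, 60, 15, 0.85)
  expect_equal(wr$wr_bc, (80 - 45 / 0.85) / 80 * 100, tolerance = 1e-12)
  expect_equal(round(wr$wr_bc, 2), 33.82)
  expect_equal(round(wr$wr_nc, 2), 29.41)
  expect_equal(wr$wr_hmr, 20)
  wrc <- washout_rates(100, 20, 0, 0, 1)
  expect_equal(wrc$wr_bc, 100); expect_equal(wrc$wr_nc, 100)
  expect_false(wrc$wr_hmr_defined)  # zero late mediastinum
  # undefined flags propagate instead of silent zeros
  wru <- washout_rates(10, 15, 5, 4, 1)
  expect_false(wru$wr_bc_defined)
  expect_true(is.na(wru$wr_bc))
  expect_true(wru$wr_nc_defined)
})

test_that("washout-rate boundary classification assigns the cutoff as abnormal", {
  expect_identical(classify_wr(34.0, 34.0), "abnormal")
  expect_identical(classify_wr(33.99, 34.0), "normal")
  expect_identical(classify_wr(30.2, 30.1), "abnormal")
  expect_error(classify_wr(NA_real_, 34), "undefined")
})

test_that("wr_hmr is invariant to common rescaling of each frame", {
  set.seed(1)
  for (i in 1:25) {
    h_e <- runif(1, 10, 100); m_e <- runif(1, 5, 40)
    h_l <- runif(1, 5, 90); m_l <- runif(1, 5, 40)
    a <- runif(1, 0.2, 5); b <- runif(1, 0.2, 5)
    w1 <- washout_rates(h_e, m_e, h_l, m_l, 0.9)$wr_hmr
    w2 <- washout_rates(a * h_e, a * m_e, b * h_l, b * m_l, 0.9)$wr_hmr
    expect_equal(w1, w2, tolerance = 1e-10)
  }
})
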