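test_that("overlap scores follow their counting definitions", {
  a <- array(FALSE, c(6, 6, 6)); a[2:3, 2:3, 2] <- TRUE
  expect_equal(unclass(seg_scores(a, a))[1:3],
               list(dice = 1, recall = 1, precision = 1))
  b <- array(FALSE, c(6, 6, 6)); b[5:6, 5:6, 5] <- TRUE
  sc <- seg_scores(a, b)
  expect_equal(sc$dice, 0); expect_equal(sc$recall, 0)
  pred <- array(FALSE, c(4, 4, 4)); pred[1:2, 1, 1] <- TRUE
  truth <- array(FALSE, c(4, 4, 4)); truth[2:3, 1, 1] <- TRUE
  sc2 <- seg_scores(pred, truth)
  expect_equal(sc2$dice, 0.5)
  expect_equal(sc2$recall, 0.5)
  expect_equal(sc2$precision, 0.5)
  expect_equal(seg_scores(array(FALSE, c(2, 2, 2)),
                          array(FALSE, c(2, 2, 2)))$dice, 1)
})

test_that("Dice is the harmonic mean of recall and precision", {
  set.seed(6)
  for (i in 1:100) {
    a <- array(runif(5^3) < 0.4, c(5, 5, 5))
    b <- array(runif(5^3) < 0.4, c(5, 5, 5))
    sc <- seg_scores(a, b)
    tp <- sum(a & b)
    if (tp == 0) next
    hm <- 2 / (1 / sc$recall + 1 / sc$precision)
    expect_equal(sc$dice, hm, tolerance = 1e-12)
    # brute-force voxel counting oracle
    expect_equal(sc$dice, 2 * tp / (sum(a) + sum(b)), tolerance = 1e-12)
  }
})

test_that("least squares matches the closed-form normal equations", {
  x <- c(0, 1, 2); y <- c(1, 3, 5)
  f <- linfit(x, y)
  expect_equal(f$slope, 2); expect_equal(f$intercept, 1)
  expect_equal(f$r_squared, 1)
  f2 <- linfit(1:10, 2 * (1:10))
  expect_equal(f2$slope, 2, tolerance = 1e-12)
  expect_equal(f2$intercept, 0, tolerance = 1e-10)
  set.seed(3)
  xr <- rnorm(40); yr <- rnorm(40)
  f3 <- linfit(xr, yr)
  sxy <- sum((xr - mean(xr)) * (yr - mean(yr)))
  sxx <- sum((xr - mean(xr))^2)
  expect_equal(f3$slope, sxy / sxx, tolerance = 1e-10)
  expect_equal(f3$intercept, mean(yr) - f3$slope * mean(xr),
               tolerance = 1e-10)
  expect_equal(f3$r_squared, cor(xr, yr)^2, tolerance = 1e-10)
  expect_lt(f3$r_squared, 0.2)  # independent noise
  expect_error(linfit(rep(1, 5), 1:5), "constant")
})

test_that("Bland-Altman reports bias, limits and the systematic-error test", {
  x <- c(1, 2, 3, 4, 5)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$p_systematic, 1)
  ba1 <- bland_altman(x, x - 5)
  expect_equal(ba1$bias, 5)
  expect_equal(ba1$sd_diff, 0)
  expect_true(ba1$degenerate)
  set.seed(11)
  d <- rnorm(50, mean = 1, sd = 1)
  ba2 <- bland_altman(d, rep(0, 50))
  expect_lt(abs(ba2$bias - 1), 0.4)
  expect_lt(ba2$p_systematic, 0.05)
  expect_equal(ba2$loa_high - ba2$loa_low, 2 * 1.96 * ba2$sd_diff)
  expect_error(bland_altman(1:4, 1:5), "paired")
})

test_that("the SPECT cutoff maps through the regression line", {
  f <- structure(list(slope = 1, intercept = 0), class = "regression_fit")
  expect_equal(derive_spect_cutoff(f, 34), 34)
  f2 <- structure(list(slope = 0.5, intercept = 13),
                  class = "regression_fit")
  expect_equal(derive_spect_cutoff(f2, 34), 30)
  f3 <- structure(list(slope = 0, intercept = 22), class = "regression_fit")
  v <- derive_spect_cutoff(f3, 34)
  expect_equal(as.numeric(v), 22)
  expect_true(attr(v, "degenerate"))
})

test_that("agreement tables honour the asymmetric boundary conventions", {
  # SPECT value equal to its cutoff is normal; planar equal is abnormal
  tab <- agreement_table(spect_wr = c(30, 30.01), planar_wr = c(33.9, 34),
                         spect_cutoff = 30, planar_cutoff = 34)
  expect_equal(tab$counts["normal", "normal"], 1)
  expect_equal(tab$counts["abnormal", "abnormal"], 1)
  # concordant pairs give 100%
  tab2 <- agreement_table(c(10, 40), c(10, 40), 30, 34)
  expect_equal(tab2$percent_agreement, 100)
  # undefined pairs are excluded and counted
  tab3 <- agreement_table(c(10, NA, 40), c(10, 20, 40), 30, 34)
  expect_equal(tab3$n, 2)
  expect_equal(tab3$n_excluded, 1)
  # percent agreement complements the off-diagonal percentages
  tabr <- agreement_from_counts(23, 1, 5, 18)
  expect_equal(tabr$percent_agreement,
               100 - tabr$percent[1, 2] - tabr$percent[2, 1],
               tolerance = 1e-12)
})

test_that("fold assignment is balanced and seed-stable", {
  f48 <- make_folds(1:48, k = 4, seed = 1)
  expect_identical(as.vector(table(f48$assignment)), rep(12L, 4))
  f47 <- make_folds(1:47, k = 4, seed = 1)
  expect_identical(sort(as.vector(table(f47$assignment))),
                   c(11L, 12L, 12L, 12L))
  expect_identical(make_folds(1:20, 4, seed = 9)$assignment,
                   make_folds(1:20, 4, seed = 9)$assignment)
  expect_error(make_folds(1:3, k = 4), "exceed")
})
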