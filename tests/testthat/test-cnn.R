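test_that("the shape algebra is enforced at construction", {
  cfg <- organ_net_config("reduced")
  expect_s3_class(cfg, "network_config")
  expect_equal(cfg$trace[1], 72L)
  # the full fully convolutional profile lands exactly on the 8-cube
  full <- organ_net_config("full")
  expect_equal(full$final_spatial, 8L)
  # a pool that does not divide the running size fails
  expect_error(network_config(layers = list(list(type = "pool", size = 5L))),
               "does not divide")
  # a conv-head stack that lands off the declared output fails
  expect_error(network_config(
    layers = lapply(1:7, function(i) list(type = "conv", kernel = 9L,
                                          channels = 4L)),
    head = "conv"), "lands on")
})

test_that("initialisation is a pure function of the seed", {
  cfg <- organ_net_config("reduced")
  n1 <- build_organ_net(cfg, seed = 7)
  n2 <- build_organ_net(cfg, seed = 7)
  n3 <- build_organ_net(cfg, seed = 8)
  expect_identical(n1$params, n2$params)
  expect_false(identical(n1$params$W_head, n3$params$W_head))
  set.seed(1)
  X <- array(runif(72^3), c(72, 72, 72, 1, 1))
  l1 <- mibgquant:::net_forward(n1, X)$logits
  l2 <- mibgquant:::net_forward(n2, X)$logits
  expect_identical(l1, l2)
  expect_identical(dim(l1), c(8L, 8L, 8L, 3L, 1L))
  p <- mibgquant:::softmax_probs(l1)
  sums <- p[, , , 1, ] + p[, , , 2, ] + p[, , , 3, ]
  expect_equal(range(sums), c(1, 1), tolerance = 1e-5)
  expect_gte(min(p), 0)
})

test_that("analytic gradients agree with central differences", {
  cfg <- network_config(input_patch = 12L, output_patch = 4L, n_classes = 2L,
                        in_channels = 2L,
                        layers = list(list(type = "pool", size = 2L),
                                      list(type = "conv", kernel = 3L,
                                           channels = 3L),
                                      list(type = "pool", size = 2L)))
  net <- build_net(cfg, seed = 9)
  set.seed(42)
  B <- 2
  X <- array(rnorm(12^3 * 2 * B), c(12, 12, 12, 2, B))
  tg <- array(runif(4^3 * 2 * B), c(4, 4, 4, 2, B))
  den <- tg[, , , 1, ] + tg[, , , 2, ]
  tg[, , , 1, ] <- tg[, , , 1, ] / den
  tg[, , , 2, ] <- tg[, , , 2, ] / den
  w <- array(rbinom(4^3 * B, 1, 0.8), c(4, 4, 4, B))
  lossfun <- function(nn) {
    fwd <- mibgquant:::net_forward(nn, X)
    mibgquant:::soft_nll(fwd$logits, tg, w)$loss
  }
  fwd <- mibgquant:::net_forward(net, X, cache = TRUE)
  ls <- mibgquant:::soft_nll(fwd$logits, tg, w)
  grads <- mibgquant:::net_backward(net, fwd, ls$grad)
  eps <- 1e-6
  for (nm in names(grads)) {
    p <- net$params[[nm]]
    for (i in sample(length(p), min(4, length(p)))) {
      n2 <- net; n2$params[[nm]][i] <- p[i] + eps
      lp <- lossfun(n2)
      n2$params[[nm]][i] <- p[i] - eps
      lm <- lossfun(n2)
      expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("patch sampling is class-balanced, seeded, and label-faithful", {
  ph <- noiseless_phantom()
  s <- ph$study
  ps1 <- sample_patches(s, n = 30, seed = 3)
  ps2 <- sample_patches(s, n = 30, seed = 3)
  expect_equal(length(ps1), 30)
  expect_identical(lapply(ps1, `[[`, "block_start"),
                   lapply(ps2, `[[`, "block_start"))
  # roughly a third of the blocks contain each organ class
  has_cls <- function(k) sum(vapply(ps1, function(x) any(x$target == k),
                                    logical(1)))
  expect_gte(has_cls(2L), 8)
  expect_gte(has_cls(3L), 8)
  expect_error(sample_patches(s, n = 0), "n must be")
  # an all-liver truth yields all-liver targets
  labs <- organ_labelmap(array(ORGAN_LABELS[["liver"]], c(64, 64, 64)))
  psl <- sample_patches(s, truth = labs, n = 6, seed = 1)
  expect_true(all(vapply(psl, function(x) all(x$target == 3L), logical(1))))
})

test_that("early stopping halts after the patience window without improvement", {
  cfg <- network_config(input_patch = 8L, output_patch = 8L, n_classes = 2L,
                        layers = list(list(type = "conv", kernel = 1L,
                                           channels = 2L)))
  net <- build_net(cfg, seed = 0)
  X <- array(0.5, c(8, 8, 8, 1, 4))
  tg <- array(0.5, c(8, 8, 8, 2, 4))
  w <- array(1, c(8, 8, 8, 4))
  provider <- function(idx) list(X = X[, , , , seq_along(idx), drop = FALSE],
                                 target = tg[, , , , seq_along(idx),
                                             drop = FALSE],
                                 weight = w[, , , seq_along(idx),
                                            drop = FALSE])
  # constant inputs and targets give an immediately flat validation loss
  tc <- train_config(batch_size = 4L, patience = 10L, max_epochs = 50L,
                     learning_rate = 1e-9, seed = 1)
  fit <- mibgquant:::fit_patch_net(net, provider, train_idx = 1:4,
                                   val_idx = 1:2, cfg = tc)
  expect_equal(nrow(fit$history), 11)  # best at epoch 1 + 10 stable epochs
})

test_that("a reduced net learns the organ layout of noiseless phantoms", {
  phs <- lapply(1:2, function(i)
    generate_phantom(phantom_params(poisson_noise = FALSE, seed = i)))
  studies <- lapply(phs, `[[`, "study")
  tc <- train_config(batch_size = 16L, patches_per_study = 12L,
                     max_epochs = 4L, val_fraction = 0, seed = 2)
  fit <- mibgquant:::train_organ_model(studies, organ_net_config("reduced"),
                                       tc)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1])
})

test_that("fourfold training uses exactly the other folds' studies", {
  phs <- lapply(1:8, function(i)
    generate_phantom(phantom_params(poisson_noise = FALSE, seed = 10 + i,
                                    blur_fwhm_mm = 0)))
  studies <- lapply(phs, `[[`, "study")
  folds <- make_folds(seq_along(studies), k = 4, seed = 1)
  tc <- train_config(batch_size = 8L, patches_per_study = 2L,
                     max_epochs = 1L, val_fraction = 0, seed = 2)
  fits <- train_organ_net(studies, folds, train_cfg = tc)
  expect_length(fits, 4)
  for (f in 1:4) {
    expect_length(fits[[f]]$train_studies, 6)
    expect_false(any(which(folds$assignment == f) %in%
                       fits[[f]]$train_studies))
  }
})

test_that("prediction tiles cover the volume and tolerate degenerate input", {
  net <- build_organ_net(seed = 1)
  zero <- spect_volume(array(0, c(64, 64, 64)))
  lm <- predict_organs(net, zero)
  expect_identical(dim(lm$labels), c(64L, 64L, 64L))
  expect_true(all(lm$labels %in% c(0L, 1L, 2L)))
})

test_that("the hoisted tiled forward pass equals the naive patch forward", {
  net <- build_organ_net(seed = 3)
  set.seed(8)
  arr <- array(runif(64^3), c(64, 64, 64))
  probs <- mibgquant:::predict_tiled(net, list(arr))
  st <- c(17L, 41L, 9L)
  X <- array(mibgquant:::extract_input_patch(list(arr), st),
             c(72, 72, 72, 1, 1))
  pp <- mibgquant:::softmax_probs(mibgquant:::net_forward(net, X)$logits)
  expect_equal(probs[st[1]:(st[1] + 7), st[2]:(st[2] + 7),
                     st[3]:(st[3] + 7), ],
               pp[, , , , 1], tolerance = 1e-12)
})
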