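# Compact 3-D patch-CNN engine: valid (unpadded) convolutions, average
# pooling, a dense or 1x1x1-convolutional classification head, softmax /
# negative log-likelihood with soft targets and per-voxel loss weights, Adam,
# and early stopping. Convolutions are evaluated as im2col patch matrices
# multiplied through BLAS, so the interpreter overhead scales with the
# kernel volume while the arithmetic runs at native speed.

#' Patch-network configuration
#'
#' Declares the shape contract of a segmentation network that maps an
#' unpadded `input_patch`^3 neighbourhood to class probabilities on the
#' central `output_patch`^3 block. Layers are applied in order; each is
#' either `list(type = "conv", kernel, channels)` (a valid 3-D convolution
#' followed by ReLU), `list(type = "pool", size)` (average pooling), or
#' `list(type = "crop", size)` (centre crop, a spatial restriction to the
#' block's neighbourhood). With
#' `head = "dense"` the final feature block feeds a fully connected layer
#' emitting the `output_patch`^3 x `n_classes` logits; with `head = "conv"`
#' the layer stack must itself land exactly on `output_patch`^3 spatially and
#' a 1x1x1 convolution maps features to class logits. The shape algebra is
#' checked here, at construction, never at run time: a stack whose valid
#' convolutions and poolings do not compose to a legal output raises an
#' error.
#'
#' @param input_patch input cube edge in voxels (default 72).
#' @param output_patch output cube edge in voxels (default 8).
#' @param n_classes number of classes (default 3: background, lungs, liver).
#' @param in_channels input channels (1 for the organ stage, 2 for the heart
#'   stage).
#' @param layers list of layer descriptors (see above). The default is the
#'   reduced desk-scale profile: pool 2, centre crop to 20 (a 40-voxel
#'   context window at half resolution), 3x3x3 convolutions of widths 4 and
#'   8, a 1x1x1 width-4 channel reduction, pool 2, dense head.
#' @param head `"dense"` or `"conv"`.
#' @return A validated object of class `network_config` with the computed
#'   per-layer spatial sizes in `$trace`.
#' @export
network_config <- function(input_patch = 72L, output_patch = 8L,
                           n_classes = 3L, in_channels = 1L,
                           layers = list(
                             list(type = "pool", size = 2L),
                             list(type = "crop", size = 20L),
                             list(type = "conv", kernel = 3L, channels = 4L),
                             list(type = "conv", kernel = 3L, channels = 8L),
                             list(type = "conv", kernel = 1L, channels = 4L),
                             list(type = "pool", size = 2L)),
                           head = c("dense", "conv")) {
  head <- match.arg(head)
  s <- as.integer(input_patch)
  trace <- s
  ch <- as.integer(in_channels)
  for (ly in layers) {
    if (ly$type == "conv") {
      s <- s - as.integer(ly$kernel) + 1L
      ch <- as.integer(ly$channels)
    } else if (ly$type == "pool") {
      if (s %% as.integer(ly$size) != 0L)
        stop(sprintf(
          "network_config: pool size %d does not divide spatial size %d",
          ly$size, s), call. = FALSE)
      s <- s %/% as.integer(ly$size)
    } else if (ly$type == "crop") {
      cs <- as.integer(ly$size)
      if (cs > s || (s - cs) %% 2L != 0L)
        stop(sprintf(
          "network_config: cannot centre-crop spatial size %d to %d", s, cs),
          call. = FALSE)
      s <- cs
    } else stop("unknown layer type: ", ly$type, call. = FALSE)
    if (s < 1L)
      stop("network_config: layer stack consumes the whole patch",
           call. = FALSE)
    trace <- c(trace, s)
  }
  if (head == "conv" && s != as.integer(output_patch))
    stop(sprintf(
      "network_config: convolutional stack lands on %d^3, not the declared output %d^3",
      s, output_patch), call. = FALSE)
  structure(list(input_patch = as.integer(input_patch),
                 output_patch = as.integer(output_patch),
                 n_classes = as.integer(n_classes),
                 in_channels = as.integer(in_channels),
                 layers = layers, head = head, trace = trace,
                 final_spatial = s, final_channels = ch),
            class = "network_config")
}

#' Training configuration
#'
#' Optimisation settings shared by the organ and heart stages: Adam with
#' initial learning rate 0.001, per-voxel negative log-likelihood loss,
#' batch size 150 patches, an 80/20 train/validation split by study, and
#' early stopping once the best validation loss has not improved by more
#' than `min_delta` for `patience` consecutive epochs. The reduced
#' desk-scale profile shipped in the tests overrides `batch_size`,
#' `max_epochs` and `patches_per_study` downwards; the defaults here are the
#' full-scale settings.
#'
#' @param batch_size patches per mini-batch (default 150).
#' @param learning_rate initial Adam step (default 0.001).
#' @param patience epochs of stable validation loss before stopping
#'   (default 10).
#' @param min_delta improvement below which the loss counts as stable
#'   (default 1e-4).
#' @param max_epochs hard epoch cap (default 100).
#' @param val_fraction fraction of training studies held out for validation
#'   (default 0.2).
#' @param patches_per_study training patches sampled per study per stage
#'   (default 64).
#' @param seed integer seed for initialisation, sampling and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 150L, learning_rate = 0.001,
                         patience = 10L, min_delta = 1e-4,
                         max_epochs = 100L, val_fraction = 0.2,
                         patches_per_study = 64L, seed = 0L) {
  stopifnot(batch_size >= 1, patience >= 1, max_epochs >= 1,
            val_fraction >= 0, val_fraction < 1, learning_rate > 0)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience), min_delta = min_delta,
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction,
                 patches_per_study = as.integer(patches_per_study),
                 seed = as.integer(seed)),
            class = "train_config")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

#' Build an untrained patch network
#'
#' Initialises weights (He-normal) for the given configuration under a fixed
#' seed; two builds with the same seed produce identical parameters.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed.
#' @return An object of class `patch_net` holding `cfg` and `params`.
#' @export
build_net <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "network_config"))
  params <- with_seed(seed, {
    ps <- list()
    cin <- cfg$in_channels
    for (i in seq_along(cfg$layers)) {
      ly <- cfg$layers[[i]]
      if (ly$type == "conv") {
        k <- ly$kernel
        ps[[paste0("W", i)]] <- he_init(c(k, k, k, cin, ly$channels),
                                        k^3 * cin)
        ps[[paste0("b", i)]] <- numeric(ly$channels)
        cin <- ly$channels
      }
    }
    if (cfg$head == "dense") {
      nin <- cfg$final_spatial^3 * cfg$final_channels
      nout <- cfg$output_patch^3 * cfg$n_classes
      ps$W_head <- matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                          nout, nin)
      ps$b_head <- numeric(nout)
    } else {
      ps$W_head <- he_init(c(1, 1, 1, cin, cfg$n_classes), cin)
      ps$b_head <- numeric(cfg$n_classes)
    }
    ps
  })
  structure(list(cfg = cfg, params = params), class = "patch_net")
}

# valid 3-D convolution via im2col + BLAS. X is (s,s,s,cin,B); the patch
# matrix has one column per kernel tap (column-major kernel order matching
# dim(W) <- c(k^3 cin, cout)) and one row per (output voxel, batch) pair.
im2col <- function(X, k) {
  d <- dim(X)
  so <- d[1] - k + 1L
  cin <- d[4]; B <- d[5]
  M <- matrix(0, so^3 * B, k^3 * cin)
  r <- 0L
  for (ci in seq_len(cin)) for (l in 1:k) for (j in 1:k) for (i in 1:k) {
    r <- r + 1L
    M[, r] <- X[i:(i + so - 1L), j:(j + so - 1L), l:(l + so - 1L), ci, ]
  }
  M
}

# reshape (so^3 B) x cout matrix into a (so,so,so,cout,B) activation array
mat_to_act <- function(M, so, B) {
  cout <- ncol(M)
  aperm(array(M, c(so, so, so, B, cout)), c(1, 2, 3, 5, 4))
}

act_to_mat <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1, 2, 3, 5, 4)), ncol = d[4])
}

conv_fwd <- function(X, W, b, relu = TRUE, keep_cols = FALSE) {
  k <- dim(W)[1]; cout <- dim(W)[5]
  so <- dim(X)[1] - k + 1L
  B <- dim(X)[5]
  M <- im2col(X, k)
  Wm <- matrix(W, ncol = cout)
  pre_mat <- M %*% Wm
  pre_mat <- sweep(pre_mat, 2, b, `+`)
  out_mat <- if (relu) pmax(pre_mat, 0) else pre_mat
  list(out = mat_to_act(out_mat, so, B),
       pre_mat = pre_mat,
       cols = if (keep_cols) M else NULL)
}

conv_bwd <- function(X, W, dOut, pre_mat, cols = NULL, relu = TRUE,
                     need_dX = TRUE) {
  k <- dim(W)[1]; cin <- dim(W)[4]; cout <- dim(W)[5]
  so <- dim(dOut)[1]
  B <- dim(dOut)[5]
  dmat <- act_to_mat(dOut)
  if (relu) dmat <- dmat * (pre_mat > 0)
  if (is.null(cols)) cols <- im2col(X, k)
  dW <- array(crossprod(cols, dmat), dim(W))
  db <- colSums(dmat)
  dX <- NULL
  if (need_dX) {
    dM <- dmat %*% t(matrix(W, ncol = cout))
    dX <- array(0, dim(X))
    r <- 0L
    for (ci in seq_len(cin)) for (l in 1:k) for (j in 1:k) for (i in 1:k) {
      r <- r + 1L
      ii <- i:(i + so - 1L); jj <- j:(j + so - 1L); ll <- l:(l + so - 1L)
      dX[ii, jj, ll, ci, ] <- dX[ii, jj, ll, ci, , drop = FALSE] +
        array(dM[, r], c(so, so, so, 1L, B))
    }
  }
  list(dX = dX, dW = dW, db = db)
}

pool_fwd <- function(X, p) {
  d <- dim(X)
  so <- d[1] %/% p
  out <- array(0, c(so, so, so, d[4], d[5]))
  for (i in 1:p) for (j in 1:p) for (l in 1:p) {
    out <- out + X[seq(i, by = p, length.out = so),
                   seq(j, by = p, length.out = so),
                   seq(l, by = p, length.out = so), , , drop = FALSE]
  }
  out / p^3
}

crop_center <- function(X, size) {
  s <- dim(X)[1]
  off <- (s - size) %/% 2L
  rng <- (off + 1L):(off + size)
  X[rng, rng, rng, , , drop = FALSE]
}

pool_bwd <- function(dOut, p, din) {
  dX <- array(0, din)
  so <- dim(dOut)[1]
  g <- dOut / p^3
  for (i in 1:p) for (j in 1:p) for (l in 1:p) {
    dX[seq(i, by = p, length.out = so),
       seq(j, by = p, length.out = so),
       seq(l, by = p, length.out = so), , ] <- g
  }
  dX
}

# leading pool layers can be evaluated once per volume instead of once per
# patch when the tiling geometry is compatible (pool product divides both
# the patch padding and the block edge); returns that product and the
# number of hoistable layers
leading_pool_hoist <- function(cfg) {
  p <- 1L; n <- 0L
  for (ly in cfg$layers) {
    if (ly$type != "pool") break
    p <- p * as.integer(ly$size); n <- n + 1L
  }
  pad <- (cfg$input_patch - cfg$output_patch) %/% 2L
  if (n > 0L && pad %% p == 0L && cfg$output_patch %% p == 0L)
    list(n = n, prod = p)
  else list(n = 0L, prod = 1L)
}

# reflection-pad each channel by the patch padding and apply the hoisted
# leading pools once; patches then reduce to small window copies
prepool_channels <- function(channels, cfg) {
  hoist <- leading_pool_hoist(cfg)
  pad <- (cfg$input_patch - cfg$output_patch) %/% 2L
  d <- dim(channels[[1]])
  idx <- lapply(1:3, function(ax)
    reflect_index(seq(1L - pad, d[ax] + pad), d[ax]))
  pooled <- lapply(channels, function(ch) {
    padded <- ch[idx[[1]], idx[[2]], idx[[3]]]
    if (hoist$n > 0L) {
      A <- array(padded, c(dim(padded), 1L, 1L))
      for (i in seq_len(hoist$n))
        A <- pool_fwd(A, cfg$layers[[i]]$size)
      array(A, dim(A)[1:3])
    } else padded
  })
  list(pooled = pooled, n_skip = hoist$n, prod = hoist$prod, pad = pad,
       win = cfg$input_patch %/% hoist$prod)
}

# window of the pre-pooled channels for a block start (1-based, must be
# congruent to 1 modulo the pool product)
prepool_window <- function(prep, block_start) {
  st <- (block_start - 1L) %/% prep$prod + 1L
  lapply(prep$pooled, function(ch)
    ch[st[1]:(st[1] + prep$win - 1L), st[2]:(st[2] + prep$win - 1L),
       st[3]:(st[3] + prep$win - 1L)])
}

# forward pass; X is (s, s, s, in_channels, B); returns logits
# (o, o, o, n_classes, B) and, if cache = TRUE, the per-layer activations.
# from_layer > 1 declares that X is already the output of layers
# 1..(from_layer - 1) (hoisted pools).
net_forward <- function(net, X, cache = FALSE, from_layer = 1L) {
  cfg <- net$cfg; ps <- net$params
  acts <- vector("list", length(cfg$layers) + 1L)
  acts[[from_layer]] <- X
  pres <- vector("list", length(cfg$layers))
  colcache <- vector("list", length(cfg$layers))
  A <- X
  for (i in seq(from_layer, length.out = length(cfg$layers) - from_layer + 1L)) {
    ly <- cfg$layers[[i]]
    if (ly$type == "conv") {
      r <- conv_fwd(A, ps[[paste0("W", i)]], ps[[paste0("b", i)]],
                    keep_cols = cache)
      A <- r$out
      if (cache) { pres[[i]] <- r$pre_mat; colcache[[i]] <- r$cols }
    } else if (ly$type == "crop") {
      A <- crop_center(A, ly$size)
    } else {
      A <- pool_fwd(A, ly$size)
    }
    if (cache) acts[[i + 1L]] <- A
  }
  B <- dim(A)[5]
  o <- cfg$output_patch
  if (cfg$head == "dense") {
    Af <- matrix(A, ncol = B)
    logits_mat <- ps$W_head %*% Af + ps$b_head
    logits <- array(logits_mat, c(o, o, o, cfg$n_classes, B))
  } else {
    s <- dim(A)[1]
    Af <- matrix(aperm(array(A, c(s^3, dim(A)[4], B)), c(2, 1, 3)),
                 nrow = dim(A)[4])
    Wm <- matrix(ps$W_head, nrow = dim(A)[4],
                 ncol = cfg$n_classes)
    logits_mat <- t(Wm) %*% Af + ps$b_head   # n_classes x (s^3 B)
    logits <- aperm(array(logits_mat, c(cfg$n_classes, s^3, B)), c(2, 1, 3))
    logits <- array(logits, c(o, o, o, cfg$n_classes, B))
  }
  out <- list(logits = logits)
  if (cache) { out$acts <- acts; out$pres <- pres; out$cols <- colcache }
  out
}

# softmax class probabilities from logits (over dim 4)
softmax_probs <- function(logits) {
  d <- dim(logits)
  nvox <- prod(d[1:3]); ncls <- d[4]; B <- d[5]
  m <- array(logits, c(nvox, ncls, B))
  mx <- m[, 1, , drop = FALSE]
  if (ncls > 1) for (cc in 2:ncls) mx <- pmax(mx, m[, cc, , drop = FALSE])
  e <- array(0, dim(m))
  for (cc in seq_len(ncls)) e[, cc, ] <- exp(m[, cc, ] - array(mx, c(nvox, B)))
  s <- array(0, c(nvox, B))
  for (cc in seq_len(ncls)) s <- s + e[, cc, ]
  for (cc in seq_len(ncls)) e[, cc, ] <- e[, cc, ] / s
  array(e, d)
}

# weighted soft-target NLL; target (o,o,o,ncls,B), weight (o,o,o,B)
soft_nll <- function(logits, target, weight) {
  d <- dim(logits)
  p <- softmax_probs(logits)
  wsum <- sum(weight)
  if (wsum <= 0) stop("all loss weights are zero: no gradient signal",
                      call. = FALSE)
  lp <- log(pmax(p, 1e-12))
  loss_per_class <- target * lp
  nvox <- prod(d[1:3])
  tm <- array(loss_per_class, c(nvox, d[4], d[5]))
  acc <- array(0, c(nvox, d[5]))
  for (cc in seq_len(d[4])) acc <- acc + tm[, cc, ]
  loss <- -sum(acc * array(weight, c(nvox, d[5]))) / wsum
  grad <- p - target
  for (cc in seq_len(d[4])) grad[, , , cc, ] <- grad[, , , cc, ] * weight
  grad <- grad / wsum
  list(loss = loss, grad = grad)
}

net_backward <- function(net, fwd, dLogits, from_layer = 1L) {
  cfg <- net$cfg; ps <- net$params
  grads <- list()
  A_last <- fwd$acts[[length(cfg$layers) + 1L]]
  B <- dim(A_last)[5]
  if (cfg$head == "dense") {
    dmat <- matrix(dLogits, ncol = B)
    Af <- matrix(A_last, ncol = B)
    grads$W_head <- dmat %*% t(Af)
    grads$b_head <- rowSums(dmat)
    dA <- array(t(ps$W_head) %*% dmat, dim(A_last))
  } else {
    s <- dim(A_last)[1]; cin <- dim(A_last)[4]
    Af <- matrix(aperm(array(A_last, c(s^3, cin, B)), c(2, 1, 3)), nrow = cin)
    dmat <- matrix(aperm(array(dLogits, c(s^3, cfg$n_classes, B)),
                         c(2, 1, 3)), nrow = cfg$n_classes)
    Wm <- matrix(ps$W_head, nrow = cin, ncol = cfg$n_classes)
    grads$W_head <- array(Af %*% t(dmat), dim(ps$W_head))
    grads$b_head <- rowSums(dmat)
    dAf <- Wm %*% dmat                     # cin x (s^3 B)
    dA <- array(aperm(array(dAf, c(cin, s^3, B)), c(2, 1, 3)),
                dim(A_last))
  }
  conv_pos <- which(vapply(cfg$layers, function(ly) ly$type == "conv",
                           logical(1)))
  conv_pos <- conv_pos[conv_pos >= from_layer]
  first_conv <- if (length(conv_pos)) min(conv_pos) else 0L
  for (i in rev(seq(from_layer, length.out =
                      length(cfg$layers) - from_layer + 1L))) {
    if (i < first_conv) break  # nothing below the first conv needs gradients
    ly <- cfg$layers[[i]]
    A_in <- fwd$acts[[i]]
    if (ly$type == "conv") {
      need_dX <- i > first_conv
      r <- conv_bwd(A_in, ps[[paste0("W", i)]], dA, fwd$pres[[i]],
                    cols = fwd$cols[[i]], need_dX = need_dX)
      grads[[paste0("W", i)]] <- r$dW
      grads[[paste0("b", i)]] <- r$db
      dA <- r$dX
    } else if (i > first_conv) {
      if (ly$type == "crop") {
        dpad <- array(0, dim(A_in))
        off <- (dim(A_in)[1] - ly$size) %/% 2L
        rng <- (off + 1L):(off + ly$size)
        dpad[rng, rng, rng, , ] <- dA
        dA <- dpad
      } else {
        dA <- pool_bwd(dA, ly$size, dim(A_in))
      }
    }
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# generic patch trainer. provider(idx) must return list(X, target, weight)
# for the given sample indices; train/val indices partition the sample set.
fit_patch_net <- function(net, provider, train_idx, val_idx, cfg) {
  stopifnot(inherits(cfg, "train_config"), length(train_idx) >= 1)
  eval_loss <- function(idx) {
    tot <- 0; nb <- 0
    for (batch in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
      d <- provider(batch)
      fwd <- net_forward(net, d$X, cache = FALSE,
                         from_layer = d$from_layer %||% 1L)
      tot <- tot + soft_nll(fwd$logits, d$target, d$weight)$loss
      nb <- nb + 1
    }
    tot / nb
  }
  state <- adam_init(net$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_loss <- Inf; best_params <- net$params; since_best <- 0L
  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample(train_idx)
      ep_loss <- 0; nb <- 0
      for (batch in split(idx, ceiling(seq_along(idx) / cfg$batch_size))) {
        d <- provider(batch)
        fl <- d$from_layer %||% 1L
        fwd <- net_forward(net, d$X, cache = TRUE, from_layer = fl)
        ls <- soft_nll(fwd$logits, d$target, d$weight)
        grads <- net_backward(net, fwd, ls$grad, from_layer = fl)
        upd <- adam_step(net$params, grads, state, cfg$learning_rate)
        net$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + ls$loss; nb <- nb + 1
      }
      ep_loss <- ep_loss / nb
      vl <- if (length(val_idx) > 0) eval_loss(val_idx) else ep_loss
      history <- rbind(history, data.frame(epoch = epoch,
                                           train_loss = ep_loss,
                                           val_loss = vl))
      if (vl < best_loss - cfg$min_delta) {
        best_loss <- vl
        best_params <- net$params
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= cfg$patience) break
      }
    }
  })
  net$params <- best_params
  list(net = net, history = history, best_val_loss = best_loss)
}

# --- patch extraction ------------------------------------------------------

# 1-based reflected index (mirror without edge repetition)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  m <- (i - 1L) %% period
  m <- ifelse(m >= n, period - m, m)
  m + 1L
}

# extract a (size^3 x channels) input patch whose central output block starts
# at block_start (1-based); channels is a list of 3-D arrays on one grid
extract_input_patch <- function(channels, block_start, input_size = 72L,
                                output_size = 8L) {
  pad <- (input_size - output_size) %/% 2L
  d <- dim(channels[[1]])
  idx <- lapply(1:3, function(ax)
    reflect_index(seq(block_start[ax] - pad, length.out = input_size), d[ax]))
  out <- array(0, c(input_size, input_size, input_size, length(channels)))
  for (ch in seq_along(channels))
    out[, , , ch] <- channels[[ch]][idx[[1]], idx[[2]], idx[[3]]]
  out
}

# assemble a training batch from per-sample descriptors
# samples: list of list(channels = list of arrays, target = array
# (o,o,o,ncls), weight = array (o,o,o), block_start = int triple)
assemble_batch <- function(samples, cfg) {
  B <- length(samples)
  s <- cfg$input_patch; o <- cfg$output_patch
  X <- array(0, c(s, s, s, cfg$in_channels, B))
  target <- array(0, c(o, o, o, cfg$n_classes, B))
  weight <- array(0, c(o, o, o, B))
  for (b in seq_len(B)) {
    sm <- samples[[b]]
    X[, , , , b] <- extract_input_patch(sm$channels, sm$block_start, s, o)
    target[, , , , b] <- sm$target
    weight[, , , b] <- sm$weight
  }
  list(X = X, target = target, weight = weight)
}

# tiled whole-volume prediction: reflection padding, non-overlapping 8^3
# blocks; returns class-probability array (dims, n_classes)
predict_tiled <- function(net, channels, batch_size = 64L) {
  cfg <- net$cfg
  d <- dim(channels[[1]])
  o <- cfg$output_patch
  stopifnot(all(d %% o == 0))
  starts <- as.matrix(expand.grid(x = seq(1, d[1], by = o),
                                  y = seq(1, d[2], by = o),
                                  z = seq(1, d[3], by = o)))
  prep <- prepool_channels(channels, cfg)
  from_layer <- prep$n_skip + 1L
  probs <- array(0, c(d, cfg$n_classes))

  # fast path: valid convolutions are translation-equivariant, so the conv
  # trunk is evaluated once over the whole (padded, pre-pooled) volume and
  # each tile's final features are read off as a window, provided every
  # remaining pooling stays grid-aligned across tiles
  if (cfg$head == "dense") {
    ps <- net$params
    dp <- dim(prep$pooled[[1]])
    A <- array(0, c(dp, cfg$in_channels, 1L))
    for (ch in seq_along(prep$pooled)) A[, , , ch, 1L] <- prep$pooled[[ch]]
    w_starts <- (starts - 1L) %/% prep$prod + 1L
    L <- cfg$input_patch %/% prep$prod
    fast <- TRUE
    for (i in seq(from_layer, length.out = length(cfg$layers) -
                    from_layer + 1L)) {
      ly <- cfg$layers[[i]]
      if (ly$type == "conv") {
        A <- conv_fwd(A, ps[[paste0("W", i)]], ps[[paste0("b", i)]])$out
        L <- L - as.integer(ly$kernel) + 1L
      } else if (ly$type == "crop") {
        w_starts <- w_starts + (L - as.integer(ly$size)) %/% 2L
        L <- as.integer(ly$size)
      } else {
        p <- as.integer(ly$size)
        if (any((w_starts - 1L) %% p != 0L) || L %% p != 0L ||
            any(dim(A)[1:3] %% p != 0L)) { fast <- FALSE; break }
        A <- pool_fwd(A, p)
        w_starts <- (w_starts - 1L) %/% p + 1L
        L <- L %/% p
      }
    }
    if (fast && L == cfg$final_spatial) {
      nb <- nrow(starts)
      Af <- matrix(0, cfg$final_spatial^3 * cfg$final_channels, nb)
      for (b in seq_len(nb)) {
        st <- w_starts[b, ]
        Af[, b] <- A[st[1]:(st[1] + L - 1L), st[2]:(st[2] + L - 1L),
                     st[3]:(st[3] + L - 1L), , 1L]
      }
      logits <- array(ps$W_head %*% Af + ps$b_head,
                      c(o, o, o, cfg$n_classes, nb))
      pb <- softmax_probs(logits)
      for (b in seq_len(nb)) {
        st <- starts[b, ]
        probs[st[1]:(st[1] + o - 1L), st[2]:(st[2] + o - 1L),
              st[3]:(st[3] + o - 1L), ] <- pb[, , , , b]
      }
      return(probs)
    }
  }

  for (grp in split(seq_len(nrow(starts)),
                    ceiling(seq_len(nrow(starts)) / batch_size))) {
    B <- length(grp)
    X <- array(0, c(prep$win, prep$win, prep$win, cfg$in_channels, B))
    for (b in seq_len(B)) {
      w <- prepool_window(prep, starts[grp[b], ])
      for (ch in seq_along(w)) X[, , , ch, b] <- w[[ch]]
    }
    p <- softmax_probs(net_forward(net, X, cache = FALSE,
                                   from_layer = from_layer)$logits)
    for (b in seq_len(B)) {
      st <- starts[grp[b], ]
      probs[st[1]:(st[1] + o - 1L), st[2]:(st[2] + o - 1L),
            st[3]:(st[3] + o - 1L), ] <- p[, , , , b]
    }
  }
  probs
}
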