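# Heart segmentation: fractional targets from paired aligned masks, the
# near-heart background-loss exclusion zone, two-channel CNN training on
# aligned early/late volumes, and heart VOI prediction.

#' Fractional heart training target
#'
#' Per-voxel heart probability formed from the early-frame heart mask and
#' the late-frame heart mask transported onto the early grid (values in
#' `[0, 1]` after linear resampling): the probability is the mean of the two
#' masks, so it is 1 where both agree on heart, 0 where both agree on
#' background, and intermediate where they disagree or interpolation is
#' fractional.
#'
#' @param mask_early numeric/logical 3-D array, early heart mask.
#' @param mask_late_aligned numeric 3-D array on the same grid, the late
#'   heart mask after registration resampling (may be fractional).
#' @return Numeric 3-D probability array in `[0, 1]`.
#' @export
fractional_target <- function(mask_early, mask_late_aligned) {
  mask_early <- as.array(mask_early) * 1.0
  mask_late_aligned <- as.array(mask_late_aligned) * 1.0
  if (!identical(dim(mask_early), dim(mask_late_aligned)))
    stop("heart masks must share a grid", call. = FALSE)
  if (any(mask_early < 0 | mask_early > 1) ||
      any(mask_late_aligned < 0 | mask_late_aligned > 1))
    stop("mask values must lie in [0, 1]", call. = FALSE)
  (mask_early + mask_late_aligned) / 2
}

#' Background-loss exclusion mask
#'
#' Returns the per-voxel loss weight for heart training: weight 0 exactly
#' for voxels that (a) are background in the target (probability 0), (b) lie
#' within `margin_vox` voxels (Chebyshev distance; 2 voxels = 1.2 cm at
#' 6.6 mm) of any voxel with positive heart probability, and (c) are not
#' labelled lungs or liver in either aligned organ map; weight 1 everywhere
#' else. This stops under-segmented heart borders from being pushed towards
#' background while keeping full supervision inside the organs.
#'
#' @param probability fractional heart target from [fractional_target()].
#' @param organs_early,organs_late_aligned [organ_labelmap()]s (or label
#'   arrays) for the two frames, the late one already aligned.
#' @param margin_vox exclusion margin in voxels (default 2).
#' @return Numeric 3-D array of 0/1 loss weights.
#' @export
loss_mask <- function(probability, organs_early, organs_late_aligned,
                      margin_vox = 2L) {
  if (margin_vox < 0) stop("margin_vox must be >= 0", call. = FALSE)
  lab_e <- if (inherits(organs_early, "organ_labelmap"))
    organs_early$labels else as.array(organs_early)
  lab_l <- if (inherits(organs_late_aligned, "organ_labelmap"))
    organs_late_aligned$labels else as.array(organs_late_aligned)
  stopifnot(identical(dim(probability), dim(lab_e)),
            identical(dim(probability), dim(lab_l)))
  near_heart <- dilate_mask(probability > 0, "full", radius = margin_vox)
  in_organ <- lab_e == ORGAN_LABELS[["lungs"]] |
    lab_e == ORGAN_LABELS[["liver"]] |
    lab_l == ORGAN_LABELS[["lungs"]] | lab_l == ORGAN_LABELS[["liver"]]
  excluded <- probability == 0 & near_heart & !in_organ
  array(1 - excluded * 1, dim(probability))
}

# assemble the per-study heart training tensors from truth masks and a
# registration transform
prepare_heart_frames <- function(study, transform) {
  stopifnot(inherits(study, "mibg_study"), !is.null(study$truth))
  sp <- study$early$spacing_mm
  heart_e <- (study$truth$early$labels == ORGAN_LABELS[["heart"]]) * 1.0
  heart_l <- (study$truth$late$labels == ORGAN_LABELS[["heart"]]) * 1.0
  aligned_heart_l <- resample(heart_l, transform, "linear", sp)
  aligned_heart_l <- pmin(pmax(aligned_heart_l, 0), 1)
  prob <- fractional_target(heart_e, aligned_heart_l)
  organs_l_aligned <- resample(study$truth$late, transform)
  w <- loss_mask(prob, study$truth$early, organs_l_aligned)
  aligned_late <- resample(study$late, transform)
  list(early = study$early$counts / volume_scale(study$early$counts),
       late = aligned_late$counts / volume_scale(aligned_late$counts),
       probability = prob, weight = w)
}

make_heart_provider <- function(frames, descriptors, net_cfg) {
  preps <- lapply(frames, function(fr)
    prepool_channels(list(fr$early, fr$late), net_cfg))
  from_layer <- preps[[1]]$n_skip + 1L
  win <- preps[[1]]$win
  function(idx) {
    B <- length(idx)
    o <- net_cfg$output_patch
    X <- array(0, c(win, win, win, 2L, B))
    target <- array(0, c(o, o, o, 2L, B))
    weight <- array(0, c(o, o, o, B))
    for (b in seq_len(B)) {
      ds <- descriptors[[idx[b]]]
      fr <- frames[[ds$frame]]
      st <- ds$block_start
      w <- prepool_window(preps[[ds$frame]], st)
      X[, , , 1L, b] <- w[[1]]
      X[, , , 2L, b] <- w[[2]]
      sel <- function(a) a[st[1]:(st[1] + 7L), st[2]:(st[2] + 7L),
                           st[3]:(st[3] + 7L)]
      pb <- sel(fr$probability)
      target[, , , 1, b] <- 1 - pb   # class 1: background
      target[, , , 2, b] <- pb       # class 2: heart
      weight[, , , b] <- sel(fr$weight)
    }
    list(X = X, target = target, weight = weight, from_layer = from_layer)
  }
}

heart_block_starts <- function(probability, n) {
  d <- dim(probability)
  pos_idx <- which(probability > 0)
  n_pos <- ceiling(n / 2)
  n_bg <- n - n_pos
  starts <- NULL
  if (length(pos_idx) > 0) {
    pick <- pos_idx[sample.int(length(pos_idx), n_pos, replace = TRUE)]
    starts <- snap_to_blocks(arrayInd(pick, d), d)
  }
  bg <- cbind(sample.int(prod(d), n_bg, replace = TRUE))
  rbind(starts, snap_to_blocks(arrayInd(bg, d), d))
}

#' Stock heart-network configuration
#'
#' The organ-network profile with two input channels (early and aligned
#' late volume) and two output classes (background, heart).
#'
#' @param profile `"reduced"` or `"full"`.
#' @return A [network_config()].
#' @export
heart_net_config <- function(profile = c("reduced", "full")) {
  organ_net_config(match.arg(profile), in_channels = 2L, n_classes = 2L)
}

#' Train the heart network on aligned study pairs
#'
#' For each study the two-channel input is the early volume and the late
#' volume resampled through the study's registration transform; the target
#' is the fractional heart probability from the two aligned truth masks and
#' the loss is soft-target negative log-likelihood multiplied by the
#' [loss_mask()] weights. Patches are drawn half from blocks containing
#' heart probability, half from background. Training, validation split and
#' early stopping follow [train_config()] exactly as in the organ stage.
#'
#' @param cohort list of [mibg_study()] objects with truth maps.
#' @param transforms list of [rigid_transform()]s aligning each study's late
#'   frame to its early frame (e.g. from [register_masks()]).
#' @param folds optional `fold_spec`; when `NULL` a single model is trained
#'   on all studies.
#' @param net_cfg a [network_config()] (default reduced heart profile).
#' @param train_cfg a [train_config()].
#' @return As [train_organ_net()]: per-fold list of `net`, `history`,
#'   `train_studies` (a single-element list when `folds` is `NULL`).
#' @export
train_heart_net <- function(cohort, transforms, folds = NULL,
                            net_cfg = heart_net_config(),
                            train_cfg = train_config()) {
  stopifnot(length(cohort) == length(transforms))
  prepared <- mapply(prepare_heart_frames, cohort, transforms,
                     SIMPLIFY = FALSE)
  if (all(vapply(prepared, function(f) sum(f$weight), numeric(1)) == 0))
    stop("all loss weights are zero: no gradient signal", call. = FALSE)
  train_one <- function(stud_idx) {
    frames <- prepared[stud_idx]
    n_stud <- length(stud_idx)
    descriptors <- list()
    with_seed(train_cfg$seed + 3L, {
      val_stud <- if (train_cfg$val_fraction > 0 && n_stud >= 2)
        sample.int(n_stud, max(1L, round(train_cfg$val_fraction * n_stud)))
      else integer(0)
      for (fi in seq_along(frames)) {
        starts <- heart_block_starts(frames[[fi]]$probability,
                                     train_cfg$patches_per_study)
        for (r in seq_len(nrow(starts)))
          descriptors[[length(descriptors) + 1L]] <-
            list(frame = fi, block_start = starts[r, ], val = fi %in% val_stud)
      }
    })
    is_val <- vapply(descriptors, `[[`, logical(1), "val")
    provider <- make_heart_provider(frames, descriptors, net_cfg)
    net <- build_net(net_cfg, train_cfg$seed)
    fit <- fit_patch_net(net, provider, which(!is_val), which(is_val),
                         train_cfg)
    list(net = fit$net, history = fit$history,
         train_studies = stud_idx)
  }
  if (is.null(folds)) return(list(train_one(seq_along(cohort))))
  stopifnot(inherits(folds, "fold_spec"))
  lapply(seq_len(folds$k), function(f) train_one(which(folds$assignment != f)))
}

#' Predict the heart VOI
#'
#' Tiled two-channel inference on the aligned early/late pair, thresholding
#' of the heart probability, and retention of the largest connected
#' component. An empty prediction is flagged rather than fabricated:
#' downstream quantitation refuses an empty VOI.
#'
#' @param model a trained heart `patch_net` (or fold result).
#' @param early a [spect_volume()].
#' @param late_aligned the late [spect_volume()] resampled onto the early
#'   grid.
#' @param threshold probability threshold (default 0.5).
#' @return A list with `voi` (logical 3-D array), `empty` flag, and
#'   `probability` (the raw heart-probability volume).
#' @export
predict_heart <- function(model, early, late_aligned, threshold = 0.5) {
  if (!inherits(model, "patch_net") && !is.null(model$net)) model <- model$net
  stopifnot(inherits(model, "patch_net"), inherits(early, "spect_volume"),
            inherits(late_aligned, "spect_volume"))
  chans <- list(early$counts / volume_scale(early$counts),
                late_aligned$counts / volume_scale(late_aligned$counts))
  probs <- predict_tiled(model, chans)
  heart_prob <- probs[, , , 2]
  voi <- heart_prob >= threshold
  if (!any(voi))
    return(list(voi = voi, empty = TRUE, probability = heart_prob))
  voi <- largest_component(voi)
  list(voi = voi, empty = FALSE, probability = heart_prob)
}
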