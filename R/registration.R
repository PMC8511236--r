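euler_matrix <- function(rotation_rad) {
  a <- rotation_rad[1]; b <- rotation_rad[2]; c <- rotation_rad[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

euler_angles <- function(R) {
  # inverse of euler_matrix (R = Rz %*% Ry %*% Rx), gimbal-safe for |b| < pi/2
  b <- -asin(max(-1, min(1, R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  c <- atan2(R[2, 1], R[1, 1])
  c(a, b, c)
}

#' Rigid (6-parameter) spatial transform
#'
#' Maps a point `x` (mm, in the fixed frame) to `R (x - c) + c + t`, with `R`
#' the rotation for Euler angles `rotation_rad` (applied x, then y, then z)
#' about the centre `c`. This is the transform [register_masks()] estimates:
#' resampling the moving image at `T(x)` aligns it to the fixed grid.
#'
#' @param translation_mm numeric triple, mm.
#' @param rotation_rad numeric triple of Euler angles, radians.
#' @param center_mm rotation centre in mm (conventionally the volume centre).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_rad = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  translation_mm <- as.numeric(translation_mm)
  rotation_rad <- as.numeric(rotation_rad)
  center_mm <- as.numeric(center_mm)
  stopifnot(length(translation_mm) == 3, length(rotation_rad) == 3,
            length(center_mm) == 3,
            all(is.finite(c(translation_mm, rotation_rad, center_mm))))
  structure(list(translation_mm = translation_mm, rotation_rad = rotation_rad,
                 center_mm = center_mm, matrix = euler_matrix(rotation_rad)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%s) mm, rot = (%s) deg\n",
              paste(signif(x$translation_mm, 4), collapse = ", "),
              paste(signif(x$rotation_rad * 180 / pi, 4), collapse = ", ")))
  invisible(x)
}

#' Invert a rigid transform
#'
#' @param t a [rigid_transform()].
#' @return The inverse transform about the same centre.
#' @export
rigid_inverse <- function(t) {
  Rt <- t(t$matrix)
  rigid_transform(-as.vector(Rt %*% t$translation_mm), euler_angles(Rt),
                  t$center_mm)
}

# world coordinates (mm) of all voxel centres, as an n-voxel x 3 matrix
voxel_coords <- function(dims, spacing_mm) {
  ax <- lapply(1:3, function(k) (seq_len(dims[k]) - 0.5) * spacing_mm[k])
  cbind(rep(ax[[1]], times = dims[2] * dims[3]),
        rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
        rep(ax[[3]], each = dims[1] * dims[2]))
}

transform_points <- function(t, pts) {
  sweep(pts, 2, t$center_mm) %*% t(t$matrix) +
    rep(t$center_mm + t$translation_mm, each = nrow(pts))
}

# trilinear sampling of a 3-D array at continuous voxel-index coordinates
# (1-based, voxel centre at integer index); outside the grid reads as 0
trilinear_sample <- function(arr, ix, iy, iz) {
  d <- dim(arr)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  fx <- ix - x0; fy <- iy - y0; fz <- iz - z0
  val <- numeric(length(ix))
  gather <- function(xi, yi, zi) {
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out <- numeric(length(xi))
    out[ok] <- arr[cbind(xi[ok], yi[ok], zi[ok])]
    out
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    nz <- w > 0
    if (any(nz)) {
      v <- gather(x0[nz] + dx, y0[nz] + dy, z0[nz] + dz)
      val[nz] <- val[nz] + w[nz] * v
    }
  }
  val
}

# resample a bare array on its own grid: out(x) = arr(T(x))
apply_rigid_array <- function(arr, spacing_mm, transform,
                              interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(arr)
  pts <- transform_points(transform, voxel_coords(d, spacing_mm))
  ix <- pts[, 1] / spacing_mm[1] + 0.5
  iy <- pts[, 2] / spacing_mm[2] + 0.5
  iz <- pts[, 3] / spacing_mm[3] + 0.5
  if (interpolation == "nearest") {
    xi <- round(ix); yi <- round(iy); zi <- round(iz)
    ok <- xi >= 1 & xi <= d[1] & yi >= 1 & yi <= d[2] & zi >= 1 & zi <= d[3]
    out <- numeric(length(ix))
    out[ok] <- arr[cbind(xi[ok], yi[ok], zi[ok])]
  } else {
    out <- trilinear_sample(arr, ix, iy, iz)
  }
  array(out, d)
}

#' Resample a volume, mask or label map through a rigid transform
#'
#' Pull-back resampling on the object's own grid: the output at voxel centre
#' `x` is the input sampled at `T(x)`, so applying the transform returned by
#' [register_masks()] to the late (moving) frame aligns it to the early
#' (fixed) frame. Points mapping outside the grid read as zero.
#'
#' @param x a [spect_volume()], [organ_labelmap()], or 3-D array.
#' @param transform a [rigid_transform()].
#' @param interpolation `"linear"` for count volumes and fractional masks,
#'   `"nearest"` for categorical maps (the default is chosen per class).
#' @param spacing_mm voxel spacing, only for bare arrays.
#' @return An object of the same type as `x`.
#' @export
resample <- function(x, transform, interpolation = NULL,
                     spacing_mm = c(6.6, 6.6, 6.6)) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "spect_volume")) {
    interpolation <- interpolation %||% "linear"
    out <- apply_rigid_array(x$counts, x$spacing_mm, transform, interpolation)
    return(spect_volume(pmax(out, 0), x$spacing_mm))
  }
  if (inherits(x, "organ_labelmap")) {
    interpolation <- interpolation %||% "nearest"
    if (interpolation != "nearest")
      stop("categorical label maps must use nearest-neighbour resampling",
           call. = FALSE)
    out <- apply_rigid_array(x$labels, x$spacing_mm, transform, "nearest")
    return(organ_labelmap(out, x$spacing_mm))
  }
  interpolation <- interpolation %||% "linear"
  apply_rigid_array(as.array(x), spacing_mm, transform, interpolation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Union lung+liver binary mask
#'
#' The registration stage works on the binary union of the lung and liver
#' labels; heart and background voxels are excluded.
#'
#' @param map an [organ_labelmap()].
#' @return A logical 3-D array.
#' @export
to_binary_union <- function(map) {
  stopifnot(inherits(map, "organ_labelmap"))
  map$labels == ORGAN_LABELS[["lungs"]] | map$labels == ORGAN_LABELS[["liver"]]
}

# separable Gaussian smoothing in voxel units (zero-padded, normalised kernel)
gaussian_smooth_vox <- function(arr, sigma_vox) {
  if (all(sigma_vox <= 0)) return(arr)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigma_vox[min(ax, length(sigma_vox))]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1-D zero-padded convolution along one axis of a 3-D array
convolve_axis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  n <- d[axis]
  acc <- array(0, d)
  idx_full <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  for (off in -r:r) {
    w <- kernel[off + r + 1L]
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    idx_dst <- idx_full; idx_src <- idx_full
    idx_dst[[axis]] <- which(ok)
    idx_src[[axis]] <- src[ok]
    acc[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      acc[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
      w * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  }
  acc
}

central_gradient <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (ax in 1:3) {
    n <- d[ax]
    idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    ip <- idx; im <- idx
    ip[[ax]] <- pmin(idx[[ax]] + 1L, n)
    im[[ax]] <- pmax(idx[[ax]] - 1L, 1L)
    denom <- (pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L)) *
      spacing[ax]
    ga <- (arr[ip[[1]], ip[[2]], ip[[3]]] - arr[im[[1]], im[[2]], im[[3]]])
    # per-plane denominator: one-sided at the grid ends, central inside
    if (ax == 1) ga <- ga / denom
    if (ax == 2) ga <- ga / rep(denom, each = d[1])
    if (ax == 3) ga <- ga / rep(denom, each = d[1] * d[2])
    g[[ax]] <- ga
  }
  g
}

#' Rigidly register two binary organ masks
#'
#' Estimates the rigid transform aligning a moving mask to a fixed mask by
#' minimising the full-grid mean-squared difference between the (lightly
#' smoothed) masks with plain gradient descent: both masks are smoothed with
#' an isotropic Gaussian (`sigma_vox` voxels) so the binary metric has a
#' usable analytic gradient, the moving image and its spatial gradient are
#' trilinearly sampled at the transformed voxel centres, and the step length
#' decays as `1/(1 + 0.01 k)` from a first step of `step_mm` millimetres.
#' Rotations are internally scaled by a 100 mm lever arm so that all six
#' parameters are optimised on a commensurate scale. The best (lowest-metric)
#' iterate is returned, so the final metric never exceeds the metric at the
#' identity.
#'
#' @param fixed,moving logical or numeric 3-D arrays (same shape), typically
#'   from [to_binary_union()]; both must be non-empty.
#' @param spacing_mm voxel spacing in mm.
#' @param n_iter number of gradient-descent iterations (default 200).
#' @param step_mm initial step length in mm-equivalents (default 2).
#' @param sigma_vox Gaussian pre-smoothing of both masks, voxels (default 1).
#' @return A list with `transform` (a [rigid_transform()]), `metric` (final
#'   mean-squared difference), and `metric_history`.
#' @export
register_masks <- function(fixed, moving, spacing_mm = c(6.6, 6.6, 6.6),
                           n_iter = 200L, step_mm = 2, sigma_vox = 1) {
  fixed <- as.array(fixed) * 1.0
  moving <- as.array(moving) * 1.0
  if (!identical(dim(fixed), dim(moving)))
    stop("fixed and moving masks must share a grid", call. = FALSE)
  if (sum(fixed) == 0 || sum(moving) == 0)
    stop("cannot register empty masks", call. = FALSE)
  d <- dim(fixed)
  Fm <- gaussian_smooth_vox(fixed, rep(sigma_vox, 3))
  Mv <- gaussian_smooth_vox(moving, rep(sigma_vox, 3))
  G <- central_gradient(Mv, spacing_mm)
  center <- d * spacing_mm / 2

  # the residual is provably zero wherever both masks (and any displaced
  # version within the margin) vanish, so the full-grid mean square is
  # evaluated over the joint support bounding box plus a motion margin
  supp <- which(Fm > 1e-4 | Mv > 1e-4)
  co <- arrayInd(supp, d)
  margin <- 6L
  lo <- pmax(apply(co, 2, min) - margin, 1L)
  hi <- pmin(apply(co, 2, max) + margin, d)
  box_dims <- hi - lo + 1L
  n_full <- prod(d)
  ax <- lapply(1:3, function(k) (seq(lo[k], hi[k]) - 0.5) * spacing_mm[k])
  pts0 <- cbind(rep(ax[[1]], times = box_dims[2] * box_dims[3]),
                rep(rep(ax[[2]], each = box_dims[1]), times = box_dims[3]),
                rep(ax[[3]], each = box_dims[1] * box_dims[2]))
  pts0c <- sweep(pts0, 2, center)
  Fv <- as.vector(Fm[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])

  # flat-index trilinear gather shared across the mask and its gradients:
  # one matrix row-gather per cube corner serves all four sampled fields
  s1 <- 1; s2 <- d[1]; s3 <- d[1] * d[2]
  fields <- cbind(as.vector(Mv), as.vector(G[[1]]), as.vector(G[[2]]),
                  as.vector(G[[3]]))
  sample_all <- function(ix, iy, iz) {
    x0 <- pmin(pmax(floor(ix), 1), d[1] - 1)
    y0 <- pmin(pmax(floor(iy), 1), d[2] - 1)
    z0 <- pmin(pmax(floor(iz), 1), d[3] - 1)
    fx <- pmin(pmax(ix - x0, 0), 1)
    fy <- pmin(pmax(iy - y0, 0), 1)
    fz <- pmin(pmax(iz - z0, 0), 1)
    base <- (x0 - 1) * s1 + (y0 - 1) * s2 + (z0 - 1) * s3 + 1
    acc <- matrix(0, length(ix), 4L)
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
        (if (dz) fz else 1 - fz)
      acc <- acc + w * fields[base + dx * s1 + dy * s2 + dz * s3, ]
    }
    list(acc[, 1], acc[, 2], acc[, 3], acc[, 4])
  }

  lever <- 100  # mm; puts radians on a millimetre-commensurate scale
  dR <- function(rot) {
    a <- rot[1]; b <- rot[2]; c <- rot[3]
    Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
    Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
    Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
    dRx <- matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
    dRy <- matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3, 3)
    dRz <- matrix(c(-sin(c), cos(c), 0, -cos(c), -sin(c), 0, 0, 0, 0), 3, 3)
    list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
  }
  eval_state <- function(q) {
    rot <- q[4:6] / lever
    R <- euler_matrix(rot)
    pts <- pts0c %*% t(R) + rep(center + q[1:3], each = nrow(pts0c))
    ix <- pts[, 1] / spacing_mm[1] + 0.5
    iy <- pts[, 2] / spacing_mm[2] + 0.5
    iz <- pts[, 3] / spacing_mm[3] + 0.5
    sm <- sample_all(ix, iy, iz)
    r <- sm[[1]] - Fv
    rg <- cbind(r * sm[[2]], r * sm[[3]], r * sm[[4]])
    grad <- numeric(6)
    grad[1:3] <- 2 * colSums(rg) / n_full
    # rotation gradient via the moment matrix M_ij = sum r g_i (x - c)_j
    M <- crossprod(rg, pts0c)
    dRs <- dR(rot)
    for (k in 1:3)
      grad[3 + k] <- 2 * sum(dRs[[k]] * M) / n_full / lever
    list(metric = sum(r^2) / n_full, grad = grad)
  }

  q <- numeric(6)  # (tx, ty, tz [mm], rx, ry, rz [rad * lever])
  st <- eval_state(q)
  g0 <- sqrt(sum(st$grad^2))
  history <- numeric(n_iter + 1)
  history[1] <- st$metric
  best_q <- q; best_metric <- st$metric
  if (g0 > 0) {
    scale <- step_mm / g0
    for (k in seq_len(n_iter)) {
      q <- q - (scale / (1 + 0.01 * (k - 1))) * st$grad
      st <- eval_state(q)
      history[k + 1] <- st$metric
      if (st$metric < best_metric) {
        best_metric <- st$metric
        best_q <- q
      }
    }
  } else {
    history <- history[1]
  }
  list(transform = rigid_transform(best_q[1:3], best_q[4:6] / lever, center),
       metric = best_metric, metric_history = history)
}
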