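# Synthetic thoracic phantom: geometric organs with the uptake hierarchy,
# washout, physical decay, collimator blur, Poisson counting noise and
# inter-scan rigid motion that the quantitation pipeline assumes.

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Phantom parameters
#'
#' Geometry is a torso modelled as an elliptic cylinder of mediastinal-level
#' background tissue containing a spherical heart (wall plus low-count
#' cavity), two ellipsoidal lungs and an ellipsoidal liver abutting the
#' inferior heart wall. Units are mm and counts/voxel at the early time
#' point. The default uptake hierarchy (liver ~ heart > lungs > mediastinum)
#' and the geometry are documented package choices; set
#' `wall_thickness_mm >= heart_outer_radius_mm` for a solid heart.
#'
#' Washout acts per truth region: every heart-labelled voxel (wall and
#' cavity) loses `washout_fraction_heart` of its early counts between frames,
#' all other tissue loses `washout_fraction_background`, and the whole late
#' frame additionally decays by `0.5^(dt/13)` (the 13-h physical half-life
#' constant used throughout the package). The late frame is then moved by the
#' `intershift` rigid transform, blurred, and (optionally) Poisson-sampled.
#'
#' @param heart_center_mm,heart_outer_radius_mm,wall_thickness_mm heart
#'   geometry (sphere centre, outer radius, wall thickness).
#' @param lung_centers_mm 2x3 matrix of lung ellipsoid centres.
#' @param lung_radii_mm semi-axes shared by both lungs.
#' @param liver_center_mm,liver_radii_mm liver ellipsoid.
#' @param body_center_xy_mm,body_radii_xy_mm,body_z_range_mm torso cylinder.
#' @param uptake_heart,uptake_liver,uptake_lungs,uptake_mediastinum mean
#'   early counts/voxel per tissue (the heart cavity takes the mediastinal
#'   value).
#' @param washout_fraction_heart,washout_fraction_background fraction of
#'   counts lost between frames, in `[0, 1]`.
#' @param blur_fwhm_mm isotropic Gaussian collimator blur (FWHM).
#' @param poisson_noise logical; Poisson-sample both frames and planars.
#' @param intershift_translation_mm,intershift_rotation_rad rigid patient
#'   motion applied to the late frame.
#' @param injected_dose_mbq,body_weight_kg,t_early_h,t_late_h study metadata.
#' @param dim_vox,spacing_mm grid definition (default 64^3 at 6.6 mm).
#' @param seed integer seed driving all randomness of one phantom.
#' @return A validated list of class `phantom_params`.
#' @export
phantom_params <- function(heart_center_mm = c(211.2, 240, 260),
                           heart_outer_radius_mm = 45,
                           wall_thickness_mm = 15,
                           lung_centers_mm = rbind(c(120, 200, 270),
                                                   c(302.4, 200, 270)),
                           lung_radii_mm = c(45, 65, 85),
                           liver_center_mm = c(270, 230, 158),
                           liver_radii_mm = c(75, 60, 55),
                           body_center_xy_mm = c(211.2, 211.2),
                           body_radii_xy_mm = c(150, 105),
                           body_z_range_mm = c(40, 382),
                           uptake_heart = 100,
                           uptake_liver = 100,
                           uptake_lungs = 20,
                           uptake_mediastinum = 10,
                           washout_fraction_heart = 0.25,
                           washout_fraction_background = 0.05,
                           blur_fwhm_mm = 15,
                           poisson_noise = TRUE,
                           intershift_translation_mm = c(0, 0, 0),
                           intershift_rotation_rad = c(0, 0, 0),
                           injected_dose_mbq = 111,
                           body_weight_kg = 61.1,
                           t_early_h = 0.3,
                           t_late_h = 3.3,
                           dim_vox = c(64L, 64L, 64L),
                           spacing_mm = c(6.6, 6.6, 6.6),
                           seed = 0L) {
  p <- as.list(environment())
  up <- c(p$uptake_heart, p$uptake_liver, p$uptake_lungs, p$uptake_mediastinum)
  if (any(!is.finite(up)) || any(up < 0))
    stop_validation("uptake", "all uptakes must be finite and >= 0")
  wf <- c(p$washout_fraction_heart, p$washout_fraction_background)
  if (any(wf < 0) || any(wf > 1))
    stop_validation("washout_fraction", "must be in [0, 1]")
  if (p$heart_outer_radius_mm <= 0 || p$wall_thickness_mm <= 0 ||
      any(p$lung_radii_mm <= 0) || any(p$liver_radii_mm <= 0) ||
      any(p$body_radii_xy_mm <= 0))
    stop_validation("radii", "all radii must be > 0")
  extent <- p$dim_vox * p$spacing_mm
  inside <- function(lo, hi) all(lo >= 0) && all(hi <= extent)
  ok <- inside(p$heart_center_mm - p$heart_outer_radius_mm,
               p$heart_center_mm + p$heart_outer_radius_mm) &&
    inside(p$liver_center_mm - p$liver_radii_mm,
           p$liver_center_mm + p$liver_radii_mm) &&
    all(apply(p$lung_centers_mm, 1, function(ctr)
      inside(ctr - p$lung_radii_mm, ctr + p$lung_radii_mm))) &&
    inside(c(p$body_center_xy_mm - p$body_radii_xy_mm, p$body_z_range_mm[1]),
           c(p$body_center_xy_mm + p$body_radii_xy_mm, p$body_z_range_mm[2]))
  if (!ok)
    stop_validation("geometry", "organs must fit inside the volume grid")
  class(p) <- "phantom_params"
  p
}

# voxel-centre coordinate arrays, one 3-D array per axis
coord_arrays <- function(dims, spacing) {
  x <- (seq_len(dims[1]) - 0.5) * spacing[1]
  y <- (seq_len(dims[2]) - 0.5) * spacing[2]
  z <- (seq_len(dims[3]) - 0.5) * spacing[3]
  list(X = array(rep(x, times = dims[2] * dims[3]), dims),
       Y = array(rep(rep(y, each = dims[1]), times = dims[3]), dims),
       Z = array(rep(z, each = dims[1] * dims[2]), dims))
}

# truth label map and noiseless early uptake map
rasterize_phantom <- function(p) {
  co <- coord_arrays(p$dim_vox, p$spacing_mm)
  ellipsoid <- function(ctr, radii) {
    ((co$X - ctr[1]) / radii[1])^2 + ((co$Y - ctr[2]) / radii[2])^2 +
      ((co$Z - ctr[3]) / radii[3])^2 <= 1
  }
  body <- ((co$X - p$body_center_xy_mm[1]) / p$body_radii_xy_mm[1])^2 +
    ((co$Y - p$body_center_xy_mm[2]) / p$body_radii_xy_mm[2])^2 <= 1 &
    co$Z >= p$body_z_range_mm[1] & co$Z <= p$body_z_range_mm[2]
  r2 <- (co$X - p$heart_center_mm[1])^2 + (co$Y - p$heart_center_mm[2])^2 +
    (co$Z - p$heart_center_mm[3])^2
  heart <- r2 <= p$heart_outer_radius_mm^2
  inner_r <- max(p$heart_outer_radius_mm - p$wall_thickness_mm, 0)
  cavity <- r2 <= inner_r^2
  lungs <- ellipsoid(p$lung_centers_mm[1, ], p$lung_radii_mm) |
    ellipsoid(p$lung_centers_mm[2, ], p$lung_radii_mm)
  liver <- ellipsoid(p$liver_center_mm, p$liver_radii_mm)

  labels <- array(0L, p$dim_vox)
  labels[lungs] <- ORGAN_LABELS[["lungs"]]
  labels[liver] <- ORGAN_LABELS[["liver"]]
  labels[heart] <- ORGAN_LABELS[["heart"]]

  uptake <- array(0, p$dim_vox)
  uptake[body] <- p$uptake_mediastinum
  uptake[labels == ORGAN_LABELS[["lungs"]]] <- p$uptake_lungs
  uptake[labels == ORGAN_LABELS[["liver"]]] <- p$uptake_liver
  uptake[heart] <- p$uptake_heart
  uptake[cavity] <- p$uptake_mediastinum
  list(labels = labels, uptake = uptake)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Generate one synthetic early/late study
#'
#' Builds the truth organ map, renders the early frame (organ uptake, blur,
#' optional Poisson sampling), applies per-region washout, the 13-h physical
#' decay and the inter-scan rigid shift to produce the late frame, projects
#' both frames to 256 x 256 anterior planar images at 2.4 mm, and bundles
#' everything into an [mibg_study()].
#'
#' @param params a [phantom_params()].
#' @return A list with `study` (an [mibg_study()] carrying the truth label
#'   maps) and `truth` (label maps, the true aligning [rigid_transform()] for
#'   the late frame, and the true heart washout fraction).
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  ras <- rasterize_phantom(p)
  sigma_vox <- fwhm_to_sigma(p$blur_fwhm_mm) / p$spacing_mm
  dcf <- decay_correction_factor(p$t_late_h - p$t_early_h)

  heart_mask <- ras$labels == ORGAN_LABELS[["heart"]]
  late_uptake <- ras$uptake * (1 - p$washout_fraction_background)
  late_uptake[heart_mask] <- ras$uptake[heart_mask] *
    (1 - p$washout_fraction_heart)
  late_uptake <- late_uptake * dcf

  # true_transform aligns the late frame back onto the early grid; the late
  # frame itself is the early anatomy pushed through its inverse
  center <- p$dim_vox * p$spacing_mm / 2
  true_transform <- rigid_transform(p$intershift_translation_mm,
                                    p$intershift_rotation_rad, center)
  shifted <- !all(p$intershift_translation_mm == 0) ||
    !all(p$intershift_rotation_rad == 0)
  labels_late <- ras$labels
  if (shifted) {
    inv <- rigid_inverse(true_transform)
    late_uptake <- apply_rigid_array(late_uptake, p$spacing_mm, inv, "linear")
    labels_late <- apply_rigid_array(ras$labels, p$spacing_mm, inv, "nearest")
  }

  early_mean <- gaussian_smooth_vox(ras$uptake, sigma_vox)
  late_mean <- gaussian_smooth_vox(late_uptake, sigma_vox)

  planar_grid <- list(dim = c(256L, 256L), spacing_mm = c(2.4, 2.4))
  planar_early_mean <- project_anterior(
    spect_volume(early_mean, p$spacing_mm), planar_grid)
  planar_late_mean <- project_anterior(
    spect_volume(late_mean, p$spacing_mm), planar_grid)

  sample_counts <- function(mean_arr, seed_off) {
    if (!p$poisson_noise) return(mean_arr)
    with_seed(p$seed + seed_off,
              array(stats::rpois(length(mean_arr), mean_arr), dim(mean_arr)))
  }
  early <- spect_volume(sample_counts(early_mean, 1L), p$spacing_mm)
  late <- spect_volume(sample_counts(late_mean, 2L), p$spacing_mm)
  pe <- planar_image(sample_counts(planar_early_mean$counts, 3L),
                     planar_grid$spacing_mm)
  pl <- planar_image(sample_counts(planar_late_mean$counts, 4L),
                     planar_grid$spacing_mm)

  truth_maps <- list(early = organ_labelmap(ras$labels, p$spacing_mm),
                     late = organ_labelmap(labels_late, p$spacing_mm))
  meta <- acquisition_meta(p$injected_dose_mbq, p$body_weight_kg,
                           p$t_early_h, p$t_late_h)
  study <- mibg_study(early, late, pe, pl, meta, truth_maps)
  truth <- structure(list(labelmap_early = truth_maps$early,
                          labelmap_late = truth_maps$late,
                          true_transform = true_transform,
                          true_washout_fraction_heart =
                            p$washout_fraction_heart,
                          params = p),
                     class = "phantom_truth")
  list(study = study, truth = truth)
}

#' Anterior parallel-ray projection of a SPECT volume
#'
#' Sums counts along the posterior-to-anterior axis, then resamples the
#' resulting 2-D grid bilinearly onto the planar matrix (default 256 x 256 at
#' 2.4 mm, centred on the volume field of view), rescaling by the pixel-area
#' ratio so that total counts are conserved to within 1%. Row 1 of the output
#' is the most superior row.
#'
#' @param vol a [spect_volume()].
#' @param target list with `dim` (pixel matrix) and `spacing_mm`; default the
#'   standard planar grid.
#' @return A [planar_image()].
#' @export
project_anterior <- function(vol,
                             target = list(dim = c(256L, 256L),
                                           spacing_mm = c(2.4, 2.4))) {
  stopifnot(inherits(vol, "spect_volume"))
  d <- dim(vol$counts)
  proj_xz <- apply(vol$counts, c(1, 3), sum)  # [x, z], counts per 6.6-mm pixel
  src_spacing <- vol$spacing_mm[c(1, 3)]
  src_extent <- d[c(1, 3)] * src_spacing
  tgt_extent <- target$dim * target$spacing_mm
  offset <- (tgt_extent - src_extent) / 2  # centre the FOV in the planar matrix

  nr <- target$dim[1]; nc <- target$dim[2]
  # planar row r (superior -> inferior) maps to world z; column c to world x
  col_x <- (seq_len(nc) - 0.5) * target$spacing_mm[2] - offset[1]
  row_z <- (nr - seq_len(nr) + 0.5) * target$spacing_mm[1] - offset[2]
  ix <- col_x / src_spacing[1] + 0.5
  iz <- row_z / src_spacing[2] + 0.5
  IX <- rep(ix, each = nr)
  IZ <- rep(iz, times = nc)
  x0 <- floor(IX); z0 <- floor(IZ)
  fx <- IX - x0; fz <- IZ - z0
  val <- numeric(nr * nc)
  for (dx in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dz) fz else 1 - fz)
    xi <- x0 + dx; zi <- z0 + dz
    ok <- w > 0 & xi >= 1 & xi <= d[1] & zi >= 1 & zi <= d[3]
    if (any(ok))
      val[ok] <- val[ok] + w[ok] * proj_xz[cbind(xi[ok], zi[ok])]
  }
  scale <- prod(target$spacing_mm) / prod(src_spacing)
  planar_image(matrix(val * scale, nr, nc), target$spacing_mm)
}

#' Planar pixel coordinates of a world point
#'
#' Maps a world coordinate (mm, volume frame) to `(row, col)` on the planar
#' grid produced by [project_anterior()], assuming the planar field of view
#' is centred on the volume field of view. Useful for seeding the heart ROI
#' from a known 3-D heart centre.
#'
#' @param point_mm numeric triple (x, y, z) in mm; y is ignored.
#' @param vol the [spect_volume()] that was projected.
#' @param img the [planar_image()] to index into.
#' @return Numeric pair `(row, col)`.
#' @export
world_to_planar <- function(point_mm, vol, img) {
  stopifnot(inherits(vol, "spect_volume"), inherits(img, "planar_image"))
  d <- dim(img$counts)
  src_extent <- dim(vol$counts)[c(1, 3)] * vol$spacing_mm[c(1, 3)]
  offset <- (d * img$spacing_mm - src_extent) / 2
  col <- (point_mm[1] + offset[1]) / img$spacing_mm[2] + 0.5
  row <- d[1] + 0.5 - (point_mm[3] + offset[2]) / img$spacing_mm[1]
  c(row, col)
}

#' Generate a reproducible cohort of synthetic studies
#'
#' Draws per-study parameters from documented uniform ranges: heart uptake
#' 70-130 counts/voxel for normal-uptake studies versus 15-35 for
#' reduced-uptake studies (the latter yield planar HMR < 1.5 on the default
#' geometry), heart washout fraction 0.05-0.35 (normal) or 0.25-0.55
#' (reduced), background washout 0.02-0.10, body weight 45-85 kg, +-10 mm
#' heart-centre jitter, +-5 mm heart-radius jitter, inter-scan translations
#' up to +-8 mm per axis and rotations up to +-3 degrees.
#'
#' @param n number of studies (>= 1).
#' @param mix fraction of reduced-uptake studies in `[0, 1]` (default 0.35,
#'   the prevalence the generator emulates).
#' @param seed integer seed; the same `(n, mix, seed)` reproduces the cohort.
#' @param poisson_noise logical, passed to every study.
#' @return A list of `n` elements, each a `list(study, truth)` as returned by
#'   [generate_phantom()]; reduced-uptake studies carry
#'   `truth$params$reduced = TRUE`.
#' @export
generate_cohort <- function(n, mix = 0.35, seed = 0L, poisson_noise = TRUE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_validation("n", "must be >= 1")
  if (mix < 0 || mix > 1) stop_validation("mix", "must be in [0, 1]")
  n <- as.integer(n)
  n_reduced <- round(n * mix)
  draws <- with_seed(seed, {
    reduced <- sample(rep(c(TRUE, FALSE), c(n_reduced, n - n_reduced)))
    lapply(seq_len(n), function(i) {
      r <- reduced[i]
      list(reduced = r,
           uptake_heart = if (r) runif(1, 15, 35) else runif(1, 70, 130),
           wf_heart = if (r) runif(1, 0.25, 0.55) else runif(1, 0.05, 0.35),
           wf_bg = runif(1, 0.02, 0.10),
           weight = runif(1, 45, 85),
           center_jitter = runif(3, -10, 10),
           radius_jitter = runif(1, -5, 5),
           shift = runif(3, -8, 8),
           rot = runif(3, -3, 3) * pi / 180,
           study_seed = sample.int(2^20, 1))
    })
  })
  lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    p <- phantom_params(
      heart_center_mm = c(211.2, 240, 260) + dr$center_jitter,
      heart_outer_radius_mm = 45 + dr$radius_jitter,
      uptake_heart = dr$uptake_heart,
      washout_fraction_heart = dr$wf_heart,
      washout_fraction_background = dr$wf_bg,
      body_weight_kg = dr$weight,
      poisson_noise = poisson_noise,
      intershift_translation_mm = dr$shift,
      intershift_rotation_rad = dr$rot,
      seed = dr$study_seed)
    p$reduced <- dr$reduced
    generate_phantom(p)
  })
}
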