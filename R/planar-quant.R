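# Planar ROI quantitation: decay correction, semi-automated heart and
# mediastinal ROI placement, HMR and the three washout-rate variants.

IODINE123_HALF_LIFE_H <- 13

#' Physical decay correction factor
#'
#' `DCF = 0.5 ^ (dt / 13)` for an interval of `dt` hours between early and
#' late imaging; the early time point is taken as zero, so `DCF = 1` at
#' `dt = 0`. A 3-h interval gives 0.85 (to two decimals).
#'
#' @param dt_h hours between early and late imaging, >= 0.
#' @return Dimensionless factor in `(0, 1]`.
#' @export
decay_correction_factor <- function(dt_h) {
  if (any(!is.finite(dt_h)) || any(dt_h < 0))
    stop("dt_h must be a non-negative number of hours", call. = FALSE)
  0.5^(dt_h / IODINE123_HALF_LIFE_H)
}

#' Detect the body contour on a planar image
#'
#' For every image row, finds the leftmost and rightmost pixel whose counts
#' exceed `threshold_frac` times the image maximum; rows with no such pixel
#' are reported as empty. Width is `right - left + 1` and the midline is
#' their mean.
#'
#' @param img a [planar_image()] with at least one positive pixel.
#' @param threshold_frac fraction of the image maximum (default 0.1).
#' @return A data frame with one row per image row: `row`, `left`, `right`,
#'   `width`, `midline` (NA where the row is below threshold).
#' @export
detect_body_contour <- function(img, threshold_frac = 0.1) {
  stopifnot(inherits(img, "planar_image"))
  mx <- max(img$counts)
  if (mx <= 0)
    stop("cannot detect a body contour on an all-zero image", call. = FALSE)
  thr <- threshold_frac * mx
  hit <- img$counts > thr
  left <- apply(hit, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  right <- apply(hit, 1, function(r) if (any(r)) max(which(r)) else NA_integer_)
  data.frame(row = seq_len(nrow(img$counts)), left = left, right = right,
             width = right - left + 1L, midline = (left + right) / 2)
}

#' Rectangular ROI
#'
#' Half-open pixel bounds `[top, bottom] x [left, right]` (inclusive indices).
#'
#' @param top,bottom,left,right integer pixel bounds.
#' @param img the [planar_image()] the ROI must lie inside.
#' @return An object of class `roi_rect`.
#' @export
roi_rect <- function(top, bottom, left, right, img) {
  top <- as.integer(round(top)); bottom <- as.integer(round(bottom))
  left <- as.integer(round(left)); right <- as.integer(round(right))
  if (bottom < top || right < left)
    stop("empty rectangular ROI", call. = FALSE)
  d <- dim(img$counts)
  if (top < 1L || left < 1L || bottom > d[1] || right > d[2])
    stop("rectangular ROI exceeds the image", call. = FALSE)
  structure(list(top = top, bottom = bottom, left = left, right = right),
            class = "roi_rect")
}

#' Circular ROI
#'
#' @param center numeric pair `(row, col)` in pixels.
#' @param radius_px circle radius in pixels, > 0.
#' @param img the [planar_image()] the circle must lie inside.
#' @return An object of class `roi_circle`.
#' @export
roi_circle <- function(center, radius_px, img) {
  stopifnot(length(center) == 2, radius_px > 0)
  d <- dim(img$counts)
  if (center[1] - radius_px < 0.5 || center[1] + radius_px > d[1] + 0.5 ||
      center[2] - radius_px < 0.5 || center[2] + radius_px > d[2] + 0.5)
    stop("circular ROI exceeds the image", call. = FALSE)
  structure(list(center = as.numeric(center), radius_px = radius_px),
            class = "roi_circle")
}

#' Place the mediastinal reference ROI
#'
#' A rectangle centred on the body midline whose width is 10% of the median
#' body width over the mediastinal rows and whose height is 30% of the
#' mediastinal height, anchored at the top of the mediastinal row range (the
#' upper mediastinum, clear of the heart).
#'
#' @param img a [planar_image()].
#' @param contour body contour from [detect_body_contour()].
#' @param mediastinum_rows integer row range spanning the mediastinum.
#' @param width_frac,height_frac the two sizing fractions (defaults 0.10 and
#'   0.30).
#' @return An `roi_rect`.
#' @export
place_mediastinal_roi <- function(img, contour, mediastinum_rows,
                                  width_frac = 0.10, height_frac = 0.30) {
  stopifnot(inherits(img, "planar_image"))
  rows <- intersect(mediastinum_rows, contour$row[!is.na(contour$width)])
  if (length(rows) == 0)
    stop("mediastinal row range contains no body rows", call. = FALSE)
  med_width <- stats::median(contour$width[contour$row %in% rows])
  roi_w <- round(width_frac * med_width)
  roi_h <- round(height_frac * length(rows))
  if (roi_w < 1 || roi_h < 1)
    stop("mediastinal ROI placement degenerate: ROI would be empty",
         call. = FALSE)
  midline <- stats::median(contour$midline[contour$row %in% rows])
  top <- min(rows)
  left <- round(midline - roi_w / 2)
  roi_rect(top, top + roi_h - 1L, left, left + roi_w - 1L, img)
}

#' Place the circular heart ROI from a user seed
#'
#' Starting from a seed point near the heart, the centre snaps to the
#' count-weighted centroid of a square search window around the seed, after
#' which the circle radius is fixed by the caller. This mirrors
#' point-and-click semi-automation: one click, the rest deterministic.
#'
#' @param img a [planar_image()].
#' @param center_seed numeric pair `(row, col)`.
#' @param radius_px circle radius in pixels (default 15 on the 2.4-mm grid).
#' @param search_px half-width of the centroid search window (default equals
#'   `radius_px`).
#' @return An `roi_circle`.
#' @export
place_heart_roi <- function(img, center_seed, radius_px = 15,
                            search_px = radius_px) {
  stopifnot(inherits(img, "planar_image"))
  d <- dim(img$counts)
  if (center_seed[1] < 1 || center_seed[1] > d[1] ||
      center_seed[2] < 1 || center_seed[2] > d[2])
    stop("heart seed lies outside the image", call. = FALSE)
  r0 <- max(1L, round(center_seed[1] - search_px))
  r1 <- min(d[1], round(center_seed[1] + search_px))
  c0 <- max(1L, round(center_seed[2] - search_px))
  c1 <- min(d[2], round(center_seed[2] + search_px))
  win <- img$counts[r0:r1, c0:c1, drop = FALSE]
  tot <- sum(win)
  if (tot <= 0)
    stop("heart ROI placement failed: no counts in the search window",
         call. = FALSE)
  rows <- r0:r1; cols <- c0:c1
  ctr <- c(sum(rowSums(win) * rows), sum(colSums(win) * cols)) / tot
  roi_circle(ctr, radius_px, img)
}

#' Mean counts per pixel inside an ROI
#'
#' Averages counts over pixels whose centres fall inside the ROI.
#'
#' @param img a [planar_image()].
#' @param roi an `roi_circle` or `roi_rect`.
#' @return Mean counts/pixel.
#' @export
roi_mean_counts <- function(img, roi) {
  stopifnot(inherits(img, "planar_image"))
  if (inherits(roi, "roi_rect")) {
    vals <- img$counts[roi$top:roi$bottom, roi$left:roi$right]
  } else if (inherits(roi, "roi_circle")) {
    d <- dim(img$counts)
    rows <- rep(seq_len(d[1]), times = d[2])
    cols <- rep(seq_len(d[2]), each = d[1])
    inside <- (rows - roi$center[1])^2 + (cols - roi$center[2])^2 <=
      roi$radius_px^2
    if (!any(inside)) stop("empty circular ROI", call. = FALSE)
    vals <- img$counts[inside]
  } else {
    stop("roi must be an roi_circle or roi_rect", call. = FALSE)
  }
  mean(vals)
}

#' Normalised planar heart metrics
#'
#' From mean heart counts `h` and mean mediastinal counts `m`
#' (counts/pixel):
#' `H_BC = (h - m) / DCF / (dose / BW)` (background-corrected),
#' `H = h / DCF / (dose / BW)` (uncorrected), and `HMR = h / m`.
#' Early frames use `dcf = 1`; late frames use
#' `decay_correction_factor(t_late - t_early)`.
#'
#' @param h,m mean heart and mediastinal counts/pixel, >= 0.
#' @param dcf decay correction factor in `(0, 1]`.
#' @param meta an [acquisition_meta()] supplying dose and body weight.
#' @return A list of class `heart_metrics` with `h_bc`, `h`, `hmr`, `raw_h`,
#'   `raw_m`; `hmr` is `NA` with `hmr_defined = FALSE` when `m = 0`.
#' @export
heart_metrics <- function(h, m, dcf, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (h < 0 || m < 0) stop("counts must be >= 0", call. = FALSE)
  if (dcf <= 0 || dcf > 1) stop("dcf must lie in (0, 1]", call. = FALSE)
  dose_per_kg <- meta$injected_dose_mbq / meta$body_weight_kg
  hmr_defined <- m > 0
  structure(list(
    h_bc = (h - m) / dcf / dose_per_kg,
    h = h / dcf / dose_per_kg,
    hmr = if (hmr_defined) h / m else NA_real_,
    hmr_defined = hmr_defined,
    raw_h = h, raw_m = m),
    class = "heart_metrics")
}

#' Planar washout rates
#'
#' The three conventional variants, in percent:
#' \describe{
#'   \item{WR_BC}{`[(h_e - m_e) - (h_l - m_l)/DCF] / (h_e - m_e) * 100`,
#'     background-corrected; only the late term is decay-corrected.}
#'   \item{WR_NC}{`(h_e - h_l/DCF) / h_e * 100`, no background correction.}
#'   \item{WR_HMR}{`(h_e/m_e - h_l/m_l) / (h_e/m_e) * 100`; the ratio cancels
#'     decay, so no DCF enters.}
#' }
#' Undefined cases (`h_e - m_e <= 0`, `h_e = 0`, zero mediastinal counts)
#' propagate as `NA` with the matching `*_defined` flag set `FALSE`, never
#' silently as zero: reduced-uptake studies can make `h_e - m_e`
#' non-positive.
#'
#' @param h_e,m_e,h_l,m_l early/late heart and mediastinal mean counts/pixel.
#' @param dcf decay correction factor for the early-late interval.
#' @return A list of class `washout_result` with `wr_bc`, `wr_nc`, `wr_hmr`
#'   and their `*_defined` flags.
#' @export
washout_rates <- function(h_e, m_e, h_l, m_l, dcf) {
  if (any(c(h_e, m_e, h_l, m_l) < 0))
    stop("counts must be >= 0", call. = FALSE)
  if (dcf <= 0 || dcf > 1) stop("dcf must lie in (0, 1]", call. = FALSE)
  bc_defined <- (h_e - m_e) > 0
  nc_defined <- h_e > 0
  hmr_defined <- m_e > 0 && m_l > 0
  structure(list(
    wr_bc = if (bc_defined)
      ((h_e - m_e) - (h_l - m_l) / dcf) / (h_e - m_e) * 100 else NA_real_,
    wr_nc = if (nc_defined) (h_e - h_l / dcf) / h_e * 100 else NA_real_,
    wr_hmr = if (hmr_defined)
      (h_e / m_e - h_l / m_l) / (h_e / m_e) * 100 else NA_real_,
    wr_bc_defined = bc_defined,
    wr_nc_defined = nc_defined,
    wr_hmr_defined = hmr_defined),
    class = "washout_result")
}

#' Classify a washout rate against a cutoff
#'
#' The boundary value is assigned to the abnormal group (`wr >= cutoff` is
#' abnormal), matching the ">= cutoff" column convention of the planar axis
#' in the agreement tables.
#'
#' @param wr washout rate in percent; must be defined (non-NA).
#' @param cutoff cutoff in percent.
#' @return `"normal"` or `"abnormal"`.
#' @export
classify_wr <- function(wr, cutoff) {
  if (any(is.na(wr)))
    stop("cannot classify an undefined washout rate", call. = FALSE)
  ifelse(wr >= cutoff, "abnormal", "normal")
}

# default mediastinal row range: from just below the body top (10% of body
# height down) to the row above the heart ROI
default_mediastinum_rows <- function(contour, heart_roi) {
  body_rows <- contour$row[!is.na(contour$width)]
  top <- min(body_rows)
  height <- max(body_rows) - top + 1L
  start <- top + round(0.10 * height)
  end <- floor(heart_roi$center[1] - heart_roi$radius_px) - 1L
  if (end <= start)
    stop("no mediastinal rows between the body top and the heart ROI",
         call. = FALSE)
  start:end
}

#' Full planar quantitation of one study
#'
#' Runs contour detection, heart and mediastinal ROI placement on the early
#' image, reuses the same ROIs on the late image (planar frames are assumed
#' position-consistent), and evaluates [heart_metrics()] for both frames and
#' [washout_rates()] across them.
#'
#' @param study an [mibg_study()].
#' @param heart_seed numeric `(row, col)` seed near the planar heart centre.
#' @param heart_radius_px heart ROI radius in pixels (default 15).
#' @param threshold_frac body-contour threshold fraction (default 0.1).
#' @return A list with `early`, `late` (each a `heart_metrics`), `washout`
#'   (a `washout_result`), `dcf`, and the two ROIs.
#' @export
planar_quantify <- function(study, heart_seed, heart_radius_px = 15,
                            threshold_frac = 0.1) {
  stopifnot(inherits(study, "mibg_study"))
  img_e <- study$planar_early
  img_l <- study$planar_late
  contour <- detect_body_contour(img_e, threshold_frac)
  heart <- place_heart_roi(img_e, heart_seed, heart_radius_px)
  med_rows <- default_mediastinum_rows(contour, heart)
  med <- place_mediastinal_roi(img_e, contour, med_rows)
  h_e <- roi_mean_counts(img_e, heart)
  m_e <- roi_mean_counts(img_e, med)
  h_l <- roi_mean_counts(img_l, heart)
  m_l <- roi_mean_counts(img_l, med)
  dcf <- decay_correction_factor(study$meta$t_late_h - study$meta$t_early_h)
  list(early = heart_metrics(h_e, m_e, 1, study$meta),
       late = heart_metrics(h_l, m_l, dcf, study$meta),
       washout = washout_rates(h_e, m_e, h_l, m_l, dcf),
       dcf = dcf, heart_roi = heart, mediastinal_roi = med)
}
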