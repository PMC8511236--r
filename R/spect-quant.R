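# SPECT heart-count and washout quantitation over the CNN heart VOI.

#' Mean counts per voxel inside a VOI
#'
#' Plain arithmetic mean over the VOI voxels, with no background subtraction
#' and no reference volume.
#'
#' @param vol a [spect_volume()].
#' @param voi logical 3-D array on the same grid, non-empty.
#' @return Mean counts/voxel.
#' @export
heart_mean_counts <- function(vol, voi) {
  stopifnot(inherits(vol, "spect_volume"))
  voi <- as.array(voi)
  if (!identical(dim(voi), dim(vol$counts)))
    stop("VOI must share the volume grid", call. = FALSE)
  if (!any(voi)) stop("empty heart VOI", call. = FALSE)
  mean(vol$counts[as.logical(voi)])
}

#' Normalised SPECT heart counts
#'
#' `H_CNN / DCF / (injected dose / kg body weight)`; the early frame uses
#' `dcf = 1`, the late frame `decay_correction_factor(t_late - t_early)`.
#'
#' @param h_cnn mean VOI counts/voxel.
#' @param dcf decay correction factor in `(0, 1]`.
#' @param meta an [acquisition_meta()].
#' @return The normalised value (linear in `h_cnn`).
#' @export
spect_h <- function(h_cnn, dcf, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (h_cnn < 0) stop("h_cnn must be >= 0", call. = FALSE)
  if (dcf <= 0 || dcf > 1) stop("dcf must lie in (0, 1]", call. = FALSE)
  h_cnn / dcf / (meta$injected_dose_mbq / meta$body_weight_kg)
}

#' SPECT washout rate
#'
#' `(Early H_CNN - Late H_CNN / DCF) / Early H_CNN * 100`, in percent;
#' invariant to rescaling both inputs by a common positive factor.
#'
#' @param h_early,h_late mean VOI counts/voxel in the two frames.
#' @param dcf decay correction factor for the early-late interval.
#' @return Percent washout, or `NA` with attribute `defined = FALSE` when
#'   `h_early = 0`.
#' @export
spect_wr <- function(h_early, h_late, dcf) {
  if (h_early < 0 || h_late < 0) stop("counts must be >= 0", call. = FALSE)
  if (dcf <= 0 || dcf > 1) stop("dcf must lie in (0, 1]", call. = FALSE)
  if (h_early == 0)
    return(structure(NA_real_, defined = FALSE))
  structure((h_early - h_late / dcf) / h_early * 100, defined = TRUE)
}

#' Full SPECT quantitation of one study
#'
#' Applies one heart VOI (predicted on the aligned early/late pair, so both
#' frames are averaged over identical voxel sets) to the early volume and
#' the aligned late volume, and evaluates the normalised heart counts and
#' washout rate.
#'
#' @param study an [mibg_study()].
#' @param voi logical heart VOI on the early grid.
#' @param transform the [rigid_transform()] aligning the late frame (NULL if
#'   already aligned).
#' @return A list of class `spect_heart_result`: `h_cnn_early`,
#'   `h_cnn_late`, `h_cnn_norm_early`, `h_cnn_norm_late`, `wr_cnn`, `dcf`,
#'   `voi_voxels`.
#' @export
spect_quantify <- function(study, voi, transform = NULL) {
  stopifnot(inherits(study, "mibg_study"))
  late <- if (is.null(transform)) study$late else resample(study$late,
                                                           transform)
  h_e <- heart_mean_counts(study$early, voi)
  h_l <- heart_mean_counts(late, voi)
  dcf <- decay_correction_factor(study$meta$t_late_h - study$meta$t_early_h)
  structure(list(
    h_cnn_early = h_e, h_cnn_late = h_l,
    h_cnn_norm_early = spect_h(h_e, 1, study$meta),
    h_cnn_norm_late = spect_h(h_l, dcf, study$meta),
    wr_cnn = as.numeric(spect_wr(h_e, h_l, dcf)),
    dcf = dcf, voi_voxels = sum(voi)),
    class = "spect_heart_result")
}
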