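#' Organ label codes
#'
#' Integer codes used in [organ_labelmap()] grids: background = 0, lungs = 1,
#' liver = 2, heart = 3. The heart label is present only in ground-truth maps
#' and heart-stage outputs; the lung/liver network never emits it.
#'
#' @format Named integer vector of length 4.
#' @export
ORGAN_LABELS <- c(background = 0L, lungs = 1L, liver = 2L, heart = 3L)

stop_validation <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

#' SPECT count volume
#'
#' A reconstructed 3-D single-photon emission tomography count grid. The axis
#' convention is fixed throughout the package: the first index runs left to
#' right, the second posterior to anterior, the third inferior to superior,
#' with 0-based voxel `i` centred at world coordinate `(i + 0.5) * spacing`
#' millimetres. Counts are stored as non-negative reals because registration
#' resampling produces fractional values even when acquisitions are integer.
#'
#' @param counts 3-D numeric array of non-negative counts per voxel
#'   (conventionally 64 x 64 x 64).
#' @param spacing_mm numeric triple of strictly positive voxel sizes in mm;
#'   default `c(6.6, 6.6, 6.6)`.
#' @return An object of class `spect_volume` with fields `counts` and
#'   `spacing_mm`.
#' @export
spect_volume <- function(counts, spacing_mm = c(6.6, 6.6, 6.6)) {
  counts <- as.array(counts)
  if (length(dim(counts)) != 3L)
    stop_validation("counts", "must be a 3-D array")
  if (anyNA(counts) || any(counts < 0))
    stop_validation("counts", "must be non-negative and non-missing")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_validation("spacing_mm", "must be three strictly positive numbers")
  structure(list(counts = counts, spacing_mm = spacing_mm),
            class = "spect_volume")
}

#' Anterior planar count image
#'
#' A 2-D projection scintigram. Row 1 is the most superior row; columns run
#' left to right (conventionally 256 x 256 at 2.4 mm).
#'
#' @param counts 2-D numeric matrix of non-negative counts per pixel.
#' @param spacing_mm numeric pair of pixel sizes in mm; default `c(2.4, 2.4)`.
#' @return An object of class `planar_image`.
#' @export
planar_image <- function(counts, spacing_mm = c(2.4, 2.4)) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(counts < 0))
    stop_validation("counts", "must be non-negative and non-missing")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 2L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop_validation("spacing_mm", "must be two strictly positive numbers")
  structure(list(counts = counts, spacing_mm = spacing_mm),
            class = "planar_image")
}

#' Acquisition metadata
#'
#' Per-study quantities entering decay correction and dose/weight
#' normalisation: injected activity, body weight, and the early and late
#' acquisition times in hours post-injection.
#'
#' @param injected_dose_mbq injected activity in MBq, > 0.
#' @param body_weight_kg body weight in kg, > 0.
#' @param t_early_h early acquisition time, hours post-injection, >= 0.
#' @param t_late_h late acquisition time, hours post-injection, > `t_early_h`.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(injected_dose_mbq, body_weight_kg,
                             t_early_h, t_late_h) {
  num1 <- function(x, field) {
    x <- as.numeric(x)
    if (length(x) != 1L || !is.finite(x)) stop_validation(field, "must be a single finite number")
    x
  }
  dose <- num1(injected_dose_mbq, "injected_dose_mbq")
  bw <- num1(body_weight_kg, "body_weight_kg")
  te <- num1(t_early_h, "t_early_h")
  tl <- num1(t_late_h, "t_late_h")
  if (dose <= 0) stop_validation("injected_dose_mbq", "must be > 0")
  if (bw <= 0) stop_validation("body_weight_kg", "must be > 0")
  if (te < 0) stop_validation("t_early_h", "must be >= 0")
  if (tl <= te) stop_validation("t_late_h", "must be greater than t_early_h")
  structure(list(injected_dose_mbq = dose, body_weight_kg = bw,
                 t_early_h = te, t_late_h = tl),
            class = "acquisition_meta")
}

#' Organ label map
#'
#' Categorical 3-D grid on the same lattice as its [spect_volume()], with one
#' label per voxel drawn from [ORGAN_LABELS].
#'
#' @param labels 3-D integer array with values in `0:3`.
#' @param spacing_mm voxel spacing in mm, as for [spect_volume()].
#' @return An object of class `organ_labelmap`.
#' @export
organ_labelmap <- function(labels, spacing_mm = c(6.6, 6.6, 6.6)) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L)
    stop_validation("labels", "must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(!labels %in% ORGAN_LABELS))
    stop_validation("labels", "values must be in {0 background, 1 lungs, 2 liver, 3 heart}")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop_validation("spacing_mm", "must be three strictly positive numbers")
  structure(list(labels = labels, spacing_mm = spacing_mm),
            class = "organ_labelmap")
}

#' Paired early/late MIBG study
#'
#' Bundles the early and late SPECT volumes, the early and late anterior
#' planar images, acquisition metadata, and (optionally) ground-truth organ
#' label maps for both frames.
#'
#' @param early,late [spect_volume()] objects sharing shape and spacing.
#' @param planar_early,planar_late [planar_image()] objects.
#' @param meta an [acquisition_meta()].
#' @param truth optional list with elements `early` and `late`, each an
#'   [organ_labelmap()] aligned to the corresponding volume.
#' @return An object of class `mibg_study`.
#' @export
mibg_study <- function(early, late, planar_early, planar_late, meta,
                       truth = NULL) {
  stopifnot(inherits(early, "spect_volume"), inherits(late, "spect_volume"),
            inherits(planar_early, "planar_image"),
            inherits(planar_late, "planar_image"),
            inherits(meta, "acquisition_meta"))
  if (!identical(dim(early$counts), dim(late$counts)) ||
      !isTRUE(all.equal(early$spacing_mm, late$spacing_mm)))
    stop_validation("late", "early and late volumes must share shape and spacing")
  if (!is.null(truth)) {
    stopifnot(is.list(truth),
              inherits(truth$early, "organ_labelmap"),
              inherits(truth$late, "organ_labelmap"))
    if (!identical(dim(truth$early$labels), dim(early$counts)))
      stop_validation("truth", "label maps must share the volume grid")
  }
  structure(list(early = early, late = late, planar_early = planar_early,
                 planar_late = planar_late, meta = meta, truth = truth),
            class = "mibg_study")
}

#' @export
print.spect_volume <- function(x, ...) {
  cat(sprintf("<spect_volume> %s voxels @ %s mm, total counts %.4g\n",
              paste(dim(x$counts), collapse = "x"),
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              sum(x$counts)))
  invisible(x)
}

#' @export
print.mibg_study <- function(x, ...) {
  cat(sprintf(
    "<mibg_study> SPECT %s, planar %s; dose %.4g MBq, BW %.4g kg, t = %.3g/%.3g h%s\n",
    paste(dim(x$early$counts), collapse = "x"),
    paste(dim(x$planar_early$counts), collapse = "x"),
    x$meta$injected_dose_mbq, x$meta$body_weight_kg,
    x$meta$t_early_h, x$meta$t_late_h,
    if (is.null(x$truth)) "" else " (+truth)"))
  invisible(x)
}

write_nifti_grid <- function(arr, spacing_mm, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  path
}

read_nifti_grid <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot load '%s': file not found", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  list(arr = array(as.numeric(img), dim = dim(img)),
       spacing_mm = RNifti::pixdim(img))
}

#' Save an organ label map as NIfTI-1
#'
#' Labels round-trip losslessly (integer codes, exact spacing in the header).
#'
#' @param map an [organ_labelmap()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return The path, invisibly usable in pipelines.
#' @seealso [load_labelmap()]
#' @export
save_labelmap <- function(map, path) {
  stopifnot(inherits(map, "organ_labelmap"))
  write_nifti_grid(map$labels, map$spacing_mm, path)
}

#' Load an organ label map saved by [save_labelmap()]
#'
#' @param path NIfTI file path.
#' @return An [organ_labelmap()].
#' @export
load_labelmap <- function(path) {
  g <- read_nifti_grid(path)
  organ_labelmap(round(g$arr), g$spacing_mm)
}

study_files <- c(early = "early_spect.nii.gz", late = "late_spect.nii.gz",
                 planar_early = "early_planar.nii.gz",
                 planar_late = "late_planar.nii.gz",
                 truth_early = "truth_early.nii.gz",
                 truth_late = "truth_late.nii.gz",
                 meta = "meta.json")

#' Save a study directory
#'
#' Writes the standard per-study layout: `early_spect.nii.gz`,
#' `late_spect.nii.gz`, `early_planar.nii.gz`, `late_planar.nii.gz`, optional
#' `truth_early.nii.gz`/`truth_late.nii.gz`, and a `meta.json` sidecar with
#' keys `injected_dose_mbq`, `body_weight_kg`, `t_early_h`, `t_late_h`.
#'
#' @param study an [mibg_study()].
#' @param dir_path output directory (created if absent).
#' @return `dir_path`, invisibly.
#' @export
save_study <- function(study, dir_path) {
  stopifnot(inherits(study, "mibg_study"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  fp <- function(name) file.path(dir_path, study_files[[name]])
  write_nifti_grid(study$early$counts, study$early$spacing_mm, fp("early"))
  write_nifti_grid(study$late$counts, study$late$spacing_mm, fp("late"))
  write_nifti_grid(study$planar_early$counts, study$planar_early$spacing_mm,
                   fp("planar_early"))
  write_nifti_grid(study$planar_late$counts, study$planar_late$spacing_mm,
                   fp("planar_late"))
  if (!is.null(study$truth)) {
    save_labelmap(study$truth$early, fp("truth_early"))
    save_labelmap(study$truth$late, fp("truth_late"))
  }
  jsonlite::write_json(study$meta[c("injected_dose_mbq", "body_weight_kg",
                                    "t_early_h", "t_late_h")],
                       file.path(dir_path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir_path)
}

#' Load a study directory
#'
#' Counterpart of [save_study()]. All metadata invariants are re-validated on
#' load; a missing required file raises an error naming that file.
#'
#' @param dir_path directory written by [save_study()] or the phantom CLI.
#' @return A validated [mibg_study()].
#' @export
load_study <- function(dir_path) {
  fp <- function(name) file.path(dir_path, study_files[[name]])
  for (name in c("early", "late", "planar_early", "planar_late", "meta")) {
    if (!file.exists(fp(name)))
      stop(sprintf("cannot load study: missing file '%s'", fp(name)),
           call. = FALSE)
  }
  meta_raw <- jsonlite::read_json(fp("meta"), simplifyVector = TRUE)
  meta <- acquisition_meta(meta_raw$injected_dose_mbq, meta_raw$body_weight_kg,
                           meta_raw$t_early_h, meta_raw$t_late_h)
  rd_vol <- function(name) {
    g <- read_nifti_grid(fp(name))
    spect_volume(g$arr, g$spacing_mm)
  }
  rd_pln <- function(name) {
    g <- read_nifti_grid(fp(name))
    planar_image(g$arr, g$spacing_mm[seq_len(2)])
  }
  truth <- NULL
  if (file.exists(fp("truth_early")) && file.exists(fp("truth_late")))
    truth <- list(early = load_labelmap(fp("truth_early")),
                  late = load_labelmap(fp("truth_late")))
  mibg_study(rd_vol("early"), rd_vol("late"), rd_pln("planar_early"),
             rd_pln("planar_late"), meta, truth)
}
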