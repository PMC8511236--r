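# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code under fixed seeds; nothing is read from
# disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# default-geometry noiseless phantom (wall + cavity heart)
noiseless_phantom <- function() {
  fixture("noiseless", function() generate_phantom(
    phantom_params(poisson_noise = FALSE)))
}

# solid-heart, high-contrast, noiseless phantom: the matched-background
# construction used for washout-recovery checks
matched_background_phantom <- function() {
  fixture("matched_bg", function() generate_phantom(
    phantom_params(poisson_noise = FALSE, wall_thickness_mm = 45,
                   uptake_heart = 150)))
}

# unblurred variant for exact (to 1e-6) washout recovery
sharp_phantom <- function() {
  fixture("sharp", function() generate_phantom(
    phantom_params(poisson_noise = FALSE, blur_fwhm_mm = 0,
                   wall_thickness_mm = 45)))
}

# heart ROI seed on the planar image, from the true 3-D heart centre
planar_heart_seed <- function(ph) {
  world_to_planar(ph$truth$params$heart_center_mm, ph$study$early,
                  ph$study$planar_early)
}

# reduced-scale training configuration used across CNN tests
reduced_train_config <- function(...) {
  train_config(batch_size = 16L, patches_per_study = 32L, max_epochs = 13L,
               patience = 5L, seed = 5L, ...)
}

# heart network trained once on a 30-study noisy cohort (used by the
# segmentation and end-to-end acceptance checks); alignment uses the
# generator's true transforms so that this fixture isolates the
# segmentation stage from registration accuracy, which is assessed
# separately
trained_heart_fixture <- function() {
  fixture("heart_model", function() {
    cohort <- generate_cohort(30, mix = 0.35, seed = 11)
    studies <- lapply(cohort, `[[`, "study")
    transforms <- lapply(cohort, function(x) x$truth$true_transform)
    fit <- train_heart_net(studies, transforms, folds = NULL,
                           train_cfg = reduced_train_config())[[1]]
    list(fit = fit, cohort = cohort)
  })
}

# centre of mass of a logical mask, in voxels
mask_com <- function(mask) colMeans(arrayInd(which(mask), dim(mask)))
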