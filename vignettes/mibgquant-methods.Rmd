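---
title: "Automated cardiac MIBG quantitation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated cardiac MIBG quantitation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mibgquant)
```

## The quantitation problem

Cardiac sympathetic innervation is imaged with the norepinephrine analogue
iodine-123 metaiodobenzylguanidine (MIBG). A study consists of an early
acquisition (minutes after injection) and a late one (3-4 h later), each
yielding an anterior planar scintigram (256 x 256 pixels, 2.4 mm) and a
reconstructed SPECT volume (64 x 64 x 64 voxels, 6.6 mm isotropic). Two
quantities summarise innervation:

* the **heart-to-mediastinum ratio**, `HMR = H / M`, with `H` and `M` the
  mean counts per pixel in a circular heart ROI and a small rectangular
  mediastinal reference ROI, and
* the **washout rate**, the percentage of cardiac tracer lost between the
  early and late frames after compensating physical decay by
  `DCF = 0.5^(dt / 13)` (13 h effective half-life constant; `DCF = 1` at the
  early time, 0.85 at a 3 h interval).

Three planar washout conventions are implemented exactly as printed in the
clinical literature:

```
WR_BC  = [(H_E - M_E) - (H_L - M_L)/DCF] / (H_E - M_E) * 100
WR_NC  = (H_E - H_L/DCF) / H_E * 100
WR_HMR = (H_E/M_E - H_L/M_L) / (H_E/M_E) * 100
```

Only the late term carries the DCF in `WR_BC` (the bracketing is taken
literally), and `WR_HMR` carries none because the ratio cancels decay.
Normalised heart counts divide by `DCF` and by injected dose (MBq) per kg
body weight. Undefined cases (`H_E - M_E <= 0`, zero mediastinal counts)
propagate as flagged missing values, never as silent zeros: severely
reduced-uptake hearts can genuinely drive the background-corrected early
signal non-positive.

The volumetric (SPECT) route replaces ROI placement with a two-step learned
segmentation: a patch CNN segments the lungs and liver on each frame; the
binary union of those masks drives a rigid registration of the late to the
early frame; a second CNN, fed the aligned early/late pair, segments the
heart; and the mean counts in the resulting heart VOI give

```
SPECT H_CNN  = H_CNN / DCF / (dose / kg BW)
SPECT WR_CNN = (Early H_CNN - Late H_CNN/DCF) / Early H_CNN * 100
```

with no background or reference volume. One VOI, predicted on the aligned
pair, is applied to both frames so that early and late means are taken over
identical voxel sets.

## The synthetic phantom

No public MIBG SPECT cohort exists, so the package ships a thoracic phantom
generator that reproduces the statistical structure the method relies on,
with every choice documented here:

* **Geometry.** A torso as an elliptic cylinder (semi-axes 150 x 105 mm) of
  mediastinal-level tissue; a spherical heart (outer radius 45 mm, 15 mm
  wall, low-count cavity) near the midline; two ellipsoidal lungs lateral to
  it; an ellipsoidal liver abutting the inferior heart wall — the abutment is
  deliberate, since separating liver from inferior myocardium is the hard
  case for threshold methods.
* **Uptake hierarchy** (mean counts/voxel at the early time): liver 100 ~
  heart 100 > lungs 20 > mediastinum 10, with the heart value drawn from
  70-130 for normal studies and 15-35 for reduced-uptake studies; on this
  geometry the reduced range renders planar HMR below 1.5 and the normal
  range above it, and cohorts draw about 35% reduced studies by default,
  matching the prevalence of advanced denervation the method must tolerate.
* **Washout** acts per truth region: heart-labelled voxels (wall and cavity)
  lose `washout_fraction_heart` (cohort draws: 0.05-0.35 normal, 0.25-0.55
  reduced), everything else loses `washout_fraction_background` (0.02-0.10),
  and the late frame decays by `0.5^(dt/13)` with default times 0.3 h and
  3.3 h (a 3 h interval, DCF 0.85).
* **Imaging model.** Isotropic Gaussian collimator blur, FWHM 15 mm by
  default (a documented stand-in for the unpublished point-spread function;
  the kernel is normalised and organs sit far enough from the grid edge that
  total counts are conserved to 1e-6). Poisson counting noise per voxel and
  per planar pixel. A rigid inter-scan shift (cohort draws: up to 8 mm per
  axis, up to 3 degrees per angle) moves the late frame; the generator
  records the aligning transform as ground truth. Anterior planars are
  parallel-ray sums along the posterior-anterior axis, bilinearly resampled
  from the 6.6 mm grid onto the 2.4 mm planar matrix with count conservation.
* **Determinism.** Every stochastic step derives from one integer seed per
  phantom; a cohort is a pure function of `(n, mix, seed)`.

What the phantom does **not** model: attenuation and scatter, anatomical
variability beyond centre/radius jitter, reconstruction artifacts, renal
or other extrathoracic uptake. Tests passing on phantoms therefore
demonstrate correctness of the formulas and the learning/registration
machinery under the stated conditions, not clinical performance.

Two special constructions appear in tests. Washout-recovery checks use a
*solid* heart (wall thickness = outer radius) with heart uptake 150: planar
background correction assumes the mediastinal ROI represents the tissue
along the heart ray, and a solid high-contrast heart makes that match hold
to within the stated two percentage points. The exact (1e-6) SPECT recovery
check additionally disables blur, because blur mixes tissues with different
washout fractions into the VOI, which is a property of the imaging model
rather than of the washout formula being verified.

## The patch networks

Two published constraints anchor the architecture: convolutions use no
padding, and a 72-cube input maps to an 8-cube output block. The layer
composition between those shapes is not recoverable from the figure, so the
configuration system treats it as user-editable and validates the shape
algebra at construction time (a stack that cannot land on the declared
output raises an error immediately, never during training).

Two profiles ship:

* `"reduced"` (the default used by all shipped tests): average-pool 2, a
  centre crop to a 20-cube (the 40-voxel neighbourhood of the output block
  at half resolution — context narrows, resolution is kept where the block
  lives), two unpadded 3-cube convolutions (widths 4 and 8) with ReLU, a
  1-cube channel-reduction convolution (width 4), average-pool 2, then a
  dense head emitting the 8-cube class logits. The pooled-and-cropped trunk
  plus dense head departs from a fully convolutional design: a stride-1
  valid 72-to-8 trunk needs on the order of thirty 3-cube layers, which is
  not trainable in minutes on one CPU. The dense head preserves the
  input/output contract while keeping desk-scale training honest.
* `"full"`: eight unpadded 9-cube convolutions whose shape algebra lands
  exactly on the 8-cube, with a 1-cube convolutional classifier — a fully
  convolutional profile for realistically sized runs.

Training uses Adam (initial rate 0.001), per-voxel negative log-likelihood,
an 80/20 train/validation split **by study** (splitting by patch would leak
neighbouring patches of one patient across the split), and early stopping
when the best validation loss has not improved by more than 1e-4 for 10
consecutive epochs ("stable" made concrete). The full-scale batch size is
150 patches; the reduced test profile uses 16. Patches are sampled
class-balanced (organ stage: background/lungs/liver centres; heart stage:
half heart-positive blocks, half background) because organ voxels are a
small minority of the volume. Patch blocks snap to the 8-cube inference
tiling so that training and inference see identical pooling alignment, and
whole-volume inference exploits the translation equivariance of valid
convolutions: the conv trunk runs once over the reflection-padded volume
and each tile reads its features from a window, which is exactly equal to
per-patch evaluation and an order of magnitude faster.

Network inputs are normalised per volume by the 99th percentile of counts,
a robust scale that makes normal- and reduced-uptake studies commensurate.

### Heart stage specifics

The training target is the *fractional label*: the mean of the early heart
mask and the registration-aligned late heart mask, giving probability 1
where they agree on heart, 0 where they agree on background, and
intermediate values (0.5 for a hard disagreement — the unique symmetric
choice) along edges. The loss weight is zero for background voxels within
2 voxels (1.2 cm; Chebyshev distance, the grid-native reading of "2
pixels", configurable) of any positive-probability voxel, unless the voxel
is labelled lungs or liver in either aligned organ map — the exclusion zone
stops under-segmented heart borders from being actively pushed to
background while keeping full supervision inside organs. The VOI is the
largest connected component of the thresholded (0.5) heart probability; an
empty VOI is flagged and downstream quantitation refuses it rather than
fabricating a region.

The phantom truth heart is the whole heart (wall plus cavity), matching the
design in which the entire cardiac region, not the myocardial wall alone,
is segmented.

## Registration

The late frame is registered to the early frame (the heart target lives on
the early grid) using the binary lung+liver union masks. The metric is the
full-grid mean-squared difference, minimised by 200 iterations of plain
gradient descent with step decay `1/(1 + 0.01 k)`; both masks are smoothed
with a 1-voxel Gaussian so the binary metric has a usable analytic
gradient, the moving mask and its spatial gradient are sampled trilinearly
at the transformed voxel centres, rotations are scaled by a 100 mm lever
arm to put all six rigid parameters on one scale, and the first step is
normalised to 2 mm. The best-metric iterate is returned, so the final
metric never exceeds the identity metric. Residuals are evaluated over the
joint support bounding box plus a motion margin — they vanish identically
elsewhere, so this equals full-image sampling at a fraction of the cost.
On noiseless phantoms the optimiser recovers 2-voxel translations to a few
hundredths of a millimetre and 5-degree rotations to about 0.15 degrees.

One numerical property of resampling is worth stating: a transform-and-invert
round trip through trilinear interpolation is exact for grid-aligned
translations, loses under 2% of total counts (L1) on volumes sampled at
about four voxels per blur FWHM, and loses around 3% at the default 15 mm
collimator blur (2.3 voxels per FWHM), where organ edges are only just
adequately sampled. Categorical maps always use nearest-neighbour
resampling, which cannot invent labels.

## Reference (non-learning) segmenter

As an independent oracle the package includes a classical segmenter: a
two-threshold Otsu split of the positive-count histogram (zeros excluded,
otherwise the background class swamps the variance criterion) separates
mediastinal, lung-level and high uptake; the high mask is opened by a
2-voxel erosion to break the blur bridge across the abutting heart-liver
boundary; components are reassigned anatomically (liver = largest,
preferring the inferior centroid; the heart-level component stays
unlabelled); lung-band components survive if lateral to the midline and at
least 200 voxels. It is deterministic and is used to sanity-check the CNN
route, never to stand in for it.

## Evaluation statistics

Dice, recall and precision are voxel-count ratios (`2TP/(2TP+FP+FN)`,
`TP/(TP+FN)`, `TP/(TP+FP)`; two empty masks score Dice 1). Regressions are
ordinary least squares with R^2 the squared Pearson correlation.
Bland-Altman reports the mean difference, its SD, limits of agreement at
1.96 SD, and a two-sided one-sample t-test of the mean difference as the
systematic-error test. The SPECT washout cutoff is derived by evaluating
the SPECT-on-planar regression at the planar cutoff and rounding to the
nearest integer percent (the clinical quoting granularity). Agreement
tables follow the asymmetric boundary conventions of their printed
counterparts literally: a SPECT value at its cutoff is normal
("<= cutoff"), a planar value at its cutoff is abnormal (">= cutoff").
Cross-validation folds partition studies at random into k groups whose
sizes differ by at most one.

## Problem sizes used by the shipped tests

The test suite and the acceptance script run everything at documented
desk-scale sizes, chosen once: 30 noisy training phantoms and 6 held-out
phantoms for the heart CNN (16 patches per study, batch 16, at most 12
epochs, patience 5); 20 phantoms for registration recovery (shifts up to 2
voxels, rotations up to 5 degrees, the full 200 iterations); a 40-study
cohort for the planar-versus-SPECT coherence regression. In the
segmentation and coherence checks the late frame is aligned with the
generator's true transform rather than a fresh registration: those checks
isolate the learning stage, and registration accuracy is established
separately by the recovery check. Heart-stage targets in those runs are
built from the generator's truth masks, mirroring the role of manual organ
contours in training.

## Known limitations

* The phantom's organ shapes are analytic; no attenuation, scatter or
  reconstruction modelling.
* The reduced network is sized for CPU minutes, not for clinical accuracy;
  the full profile is provided but not trained by the shipped tests.
* The registration step schedule is a documented fixed-decay rule, not a
  replication of adaptive step-size estimation in existing registration
  toolkits.
* smartMIBG-style mediastinal ROI placement follows the published sizing
  rule (10% of body width, 30% of mediastinal height) with the vertical
  anchor at the top of the mediastinal range — the original software's
  anchor is unpublished, so this is a documented choice, as is the fixed
  15-pixel heart ROI radius.
* Planar heart/mediastinal ROIs are placed on the early image and reused on
  the late image; planar frames are assumed position-consistent.
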