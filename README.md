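# mibgquant

Automated quantitation of cardiac sympathetic innervation from paired
early/late ¹²³I-MIBG (metaiodobenzylguanidine) scintigraphy, in R.

Clinical MIBG reporting rests on two planar quantities: the
heart-to-mediastinum ratio `HMR = H/M` and the washout rate between the
early and late acquisitions, decay-corrected by `DCF = 0.5^(Δt/13)`
(13-h half-life constant):

```
WR_BC  = [(H_E − M_E) − (H_L − M_L)/DCF] / (H_E − M_E) × 100
WR_NC  = (H_E − H_L/DCF) / H_E × 100
WR_HMR = (H_E/M_E − H_L/M_L) / (H_E/M_E) × 100
```

with heart counts normalised as `H_BC = (H − M)/DCF/(dose/kg BW)`. The
package implements this planar route (semi-automated circular heart ROI,
body-contour-derived mediastinal ROI at 10% of body width × 30% of
mediastinal height) and a fully volumetric SPECT route:

1. a 3-D patch CNN (unpadded convolutions, 72³ input → 8³ output block)
   segments the lungs and liver on each frame;
2. the binary lung+liver masks drive a rigid registration of the late to
   the early volume (mean-squares metric, full sampling, 200 gradient
   descent iterations);
3. a second CNN, fed the aligned early/late pair and trained on
   fractional heart labels (mean of the two aligned masks, with the
   background loss zeroed within 1.2 cm of the heart outside lungs and
   liver), yields a heart VOI;
4. SPECT quantities are computed from plain VOI means, with no
   background or reference region:
   `SPECT H_CNN = H_CNN/DCF/(dose/kg BW)` and
   `SPECT WR_CNN = (Early H_CNN − Late H_CNN/DCF)/Early H_CNN × 100`.

Because no public MIBG SPECT data exist, the package includes a seeded
synthetic thoracic phantom generator (64³ voxels at 6.6 mm, 256² planars
at 2.4 mm, organ uptake hierarchy, per-region washout, physical decay,
collimator blur, Poisson noise, rigid inter-scan motion, ground-truth
masks and transforms) plus the evaluation statistics used to compare the
two routes: Dice/recall/precision, OLS regression, Bland–Altman limits of
agreement, cutoff mapping, 2×2 agreement tables, and k-fold splits.

## Worked example

```r
library(mibgquant)

# a reproducible noiseless study with ground truth
ph <- generate_phantom(phantom_params(poisson_noise = FALSE))
study <- ph$study

# planar route: click-once heart seed, everything else automated
seed <- world_to_planar(ph$truth$params$heart_center_mm,
                        study$early, study$planar_early)
q <- planar_quantify(study, seed)
round(c(HMR = q$early$hmr, WR_BC = q$washout$wr_bc,
        WR_NC = q$washout$wr_nc, WR_HMR = q$washout$wr_hmr), 2)
#>    HMR  WR_BC  WR_NC WR_HMR
#>   2.79  28.71  20.20  16.01

# SPECT route with the ground-truth heart VOI
voi <- ph$truth$labelmap_early$labels == ORGAN_LABELS[["heart"]]
r <- spect_quantify(study, voi)
round(c(EarlyH = r$h_cnn_early, LateH = r$h_cnn_late, WR_CNN = r$wr_cnn), 2)
#>  EarlyH   LateH  WR_CNN
#>   58.04   37.38   24.42
```

The phantom's true heart washout fraction here is 0.25: the SPECT VOI
washout (24.4%) recovers it directly, while the planar `WR_BC` (28.7%)
carries the well-known background-correction bias of projection imaging —
exactly the gap the volumetric route is designed to close. `HMR = 2.79`
is a normal-uptake study (reduced uptake renders below 1.5).

Classifying washout against cutoffs and tabulating agreement:

```r
tab <- agreement_from_counts(23, 1, 5, 18)
tab$percent_agreement
#> [1] 87.23404
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/mibgquant.R phantom --n 10 --mix 0.35 --seed 0 --out cohort/
Rscript inst/cli/mibgquant.R planar-quant cohort/study_001 --heart-seed 108,128
Rscript inst/cli/mibgquant.R register cohort/study_001 --iters 200 --out t.json
Rscript inst/cli/mibgquant.R evaluate --table 23,1,5,18
```

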