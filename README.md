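# eatct — automated epicardial adipose tissue volumetry from non-contrast CT

Epicardial adipose tissue (EAT) is the visceral fat inside the pericardial
sac, adjacent to the myocardium and coronary arteries; its volume is a
biomarker of coronary artery disease risk.  On non-contrast CT, fat is easy
to *see* (attenuation in the −190..−30 HU window at 120 kV) but hard to
*attribute*: paracardial fat just outside the sac has identical HU, so
volumetry stands or falls with pericardium delineation — which is exactly
the part that takes a human ~20 minutes per scan.

`eatct` implements the standard fully automated two-stage pipeline for R
users (medical-image analysts, methodologists validating volumetry
pipelines):

1. **Pericardium segmentation** — a from-scratch 3D UNet++ (nested dense
   skip pathways, five levels, channels [32, 32, 64, 128, 256], instance
   norm + LeakyReLU(0.1), transposed-conv upsampling; C++ float32 GEMM
   kernels with analytic gradients behind a small reverse-mode tape),
   trained with RMSProp at a fixed learning rate on per-voxel binary
   cross-entropy over three channels: background, pericardium, and an
   auxiliary *redundant* class — fat-density voxels (−198..−80 HU) outside
   the pericardium in the inferior 20% of axial slices — that sharpens
   boundary learning in the apex region where segmentation is hardest.
2. **EAT extraction** — on the *native-resolution* image,

   `mask = pericardium ∧ (−190 ≤ HU ≤ −30)`, `V = Σ mask · v_voxel`,

   with Dice, relative volume error `100·|V_pred − V_ref|/V_ref`, Pearson
   r, Bland–Altman bias ± 1.96·SD limits, and ICC(2,1) as the evaluation
   suite.

Deterministic preprocessing (isotropic 1.6 mm resampling, centred pad/crop
to 128³, clip to [−800, 1200] HU, [0, 1] normalization) is exactly
invertible, so cube-grid predictions map back to the native grid.  A
synthetic thorax phantom generator with *analytically known* pericardium
geometry and fat volume provides ground truth for every quantitative claim,
including an end-to-end train-and-quantify check; sparse every-5th-slice
contour annotations and their shape-based (signed-distance) interpolation
are also implemented.

## Worked example

```r
library(eatct)

# a thorax phantom with known ground truth (64^3 native grid, 2.5 mm)
ph <- generate_phantom(phantom_spec())
ph$truth$eat_volume_cm3          # analytic fat volume
#> [1] 115.9762

# stage 2 on the ground-truth pericardium
res <- extract_eat(ph$volume, ph$truth$pericardium_mask)
res
#> EAT: 119.81 cm^3 (7668 voxels, window [-190, -30] HU, spacing 2.5x2.5x2.5 mm)
inferior_share(res, 0.2)         # the inferior 20% of EAT slices hold ~33%
#> [1] 0.3266823

# naive global thresholding (no pericardium constraint) fails badly:
sum(ph$volume$data >= -190 & ph$volume$data <= -30) * prod(ph$volume$spacing) / 1000
#> [1] 697.4219

# train a toy model on 20 phantoms and quantify a held-out case
cases <- generate_dataset(21, phantom_spec(shape = c(64, 64, 64),
                                           spacing = c(2.2, 2.2, 2.8)))
pre <- preprocess_config(target_spacing_mm = 2.5, cube_size = 64)
samples <- lapply(cases[1:20], function(cs) {
  pp <- apply_pipeline(cs$volume, cs$truth$pericardium_mask, pre)
  list(image = pp$image, labels = pp$labels)
})
fit <- train_unetpp(build_unetpp(unetpp_config(levels = 4,
                                               channels = c(4, 8, 16, 32),
                                               final_up_channels = 4,
                                               cube_size = 64)),
                    samples,
                    train_config(learning_rate = 1e-3, epochs = 12))
pred <- predict_pericardium(fit$model, cases[[21]]$volume, pre)
dice(pred, cases[[21]]$truth$pericardium_mask)
```

The first three numbers illustrate the core physics: the HU window inside
the true sac recovers the analytic 116 cm³ compartment to ~3% at 2.5 mm
with 10 HU noise, the apex cap concentrates a third of the volume in the
inferior fifth of EAT slices, and without the pericardium constraint the
same window picks up ~6× too much fat.

A thin CLI over the same functions lives at `inst/cli/eatct.R`
(`phantom`, `preprocess`, `train`, `predict`, `quantify`, `evaluate`), e.g.

```sh
Rscript inst/cli/eatct.R quantify --image img.nii.gz \
    --pericardium peri.nii.gz --out-dir out/
```

See `vignettes/eat-quantification.Rmd` for the model, the phantom design,
parameter defaults and numerical choices.

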