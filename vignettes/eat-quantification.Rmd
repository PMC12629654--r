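---
title: "Automated epicardial adipose tissue volumetry: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated epicardial adipose tissue volumetry: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatct)
```

## The problem

Epicardial adipose tissue (EAT) is the visceral fat enclosed by the
pericardial sac, in direct contact with the myocardium and the coronary
arteries.  Its volume is a biomarker of coronary artery disease risk, but
measuring it on non-contrast CT (e.g. calcium-scoring scans) is tedious by
hand: the pericardium is a faint, thin line, and fat attenuation alone
cannot distinguish epicardial from paracardial fat, which sits just outside
the sac at the same Hounsfield units.  Thresholding therefore only works
*after* the pericardium has been delineated.

`eatct` implements the standard two-stage automation of this measurement:

1. **Pericardium segmentation** by a 3D UNet++ voxel classifier on a
   resampled, intensity-normalized cube;
2. **EAT extraction** by HU-window thresholding (default −190..−30 HU, the
   established adipose range at 120 kV) *inside* the predicted sac, on the
   original high-resolution image.  The volume is the voxel count times the
   voxel volume.

## Geometry conventions

All "inferior fraction" logic requires an unambiguous axis convention, which
public CT data does not guarantee.  `canonicalize()` therefore reorients
every volume so voxel indices increase toward the patient's Right, Anterior
and Superior; axial slice 1 is the most inferior slice.  DICOM input is
restricted to single-frame axial series with identity in-plane orientation
(no gantry-tilt correction); anything else should be converted to NIfTI
first.

## Preprocessing

`apply_pipeline()` runs, in order:

| step | operation | parameters (defaults) |
|------|-----------|------------------------|
| 1 | isotropic resampling | trilinear for images, nearest for masks; target 1.6 mm |
| 2 | centred pad/crop | to a 128^3 cube; images padded with −800 HU, labels with 0 |
| 3 | clip + normalize | clip to [−800, 1200] HU, then map linearly onto [0, 1] |

Output shapes are `round(n * spacing / target)` per axis (half away from
zero).  The recorded `grid_transform` inverts the geometry exactly:
`invert_to_native()` un-pads, zero-fills the cropped margins and
nearest-neighbour resamples back to the native grid, so the HU thresholding
always happens at native resolution.  Two choices here were genuinely open
and are fixed by design rather than inherited: clipping/normalization runs
*after* padding (so the pad value −800 maps to 0, the air/lung background),
and the training labels are generated on the resampled grid so that
supervision and input share one grid.

### The redundant class

Segmentation accuracy is systematically worst around the cardiac apex,
where the pericardium fades and fat straddles the boundary — and the
inferior ~20% of EAT-bearing slices hold over 20% of the total EAT volume,
so apex errors translate directly into volume errors.
`make_redundant_class()` therefore adds a third training label: fat-density
voxels (−198..−80 HU) *outside* the pericardium, restricted to the
most-inferior `ceil(0.2 · nz)` axial slices.  Giving the network an explicit
name for "fat that is not EAT" sharpens the boundary decision exactly where
it is hardest.  The pericardium label always wins ties, so labels are
disjoint by construction; the redundant channel is discarded at inference.

## The segmentation network

`build_unetpp()` constructs a 3D UNet++: a five-level encoder
(channels 32, 32, 64, 128, 256 by default, stride-2 max pooling between
levels) with nested dense skip pathways.  Node $X^{i,j}$ ($j \ge 1$)
receives the concatenation of $X^{i,0..j-1}$ with a 2×2×2 transposed-conv
upsampling of $X^{i+1,j-1}$; the final upsampling into the top level
produces 32 channels.  Every block is two (3×3×3 convolution → instance
normalization → LeakyReLU, slope 0.1) stages.  The head is a 1×1×1
convolution with an independent sigmoid per class (background, pericardium,
redundant) — a multi-label reading of "binary cross-entropy" that is
consistent because the labels are disjoint; deep supervision is not used.
Training (`train_unetpp()`) is RMSProp (smoothing 0.99, eps 1e−8) at a
fixed learning rate with mini-batch 1, minimizing per-voxel BCE summed over
class channels; the per-epoch loss trace is returned and exportable as CSV.

The kernels (convolution, transposed convolution, pooling, normalization,
and their analytic gradients) are implemented in C++ with float32
GEMM-based convolutions behind a small reverse-mode tape; a naive
double-precision convolution is kept as an independent test oracle, and the
whole backward pass is verified against numeric differentiation in the test
suite.  Determinism is machine-local: a fixed seed reproduces a run exactly
on one machine, but BLAS differences may change low-order bits across
machines.

At inference, `predict_pericardium()` binarizes the pericardium channel at
probability 0.5 (configurable) and optionally keeps only the largest
26-connected component (off by default, as a flagged cleanup).

## The synthetic phantom

No CT cohort is distributed with the package, so all quantitative claims
are validated on `generate_phantom()`: a thorax-like HU landscape (lungs at
−800 HU, soft tissue ~40 HU, subcutaneous and paracardial fat ~−100 HU,
calcium 300 HU) around an ellipsoidal pericardial sac.  Inside the sac, a
heart core (scaled ellipsoid) is wrapped by a fat shell; fat occupies an
angular wedge whose fraction increases from `fat_fraction_equator` (0.4) to
`fat_fraction_apex` (0.95) in the inferior apex cap, reproducing the
inferior-heavy EAT distribution.  The wedge is defined in the normalized
elliptic angle, in which area is uniform, so the fat volume has a closed
form (`eat_volume_analytic()`): an exact integral over ellipsoid slabs that
never touches the voxel grid — the independent oracle for every recovery
test.  The pericardial line is rendered as a thin ~30 HU shell whose
contrast fades in the apex cap, mimicking the clinically hard region, and
paracardial fat plus a subcutaneous layer ensure that naive global
thresholding fails (by a factor of ~5 in volume), so the pericardium
constraint is genuinely load-bearing.

Rendering is supersampled (default 2×, i.e. 8 sub-voxels), so boundary
voxels carry realistic partial-volume-mixed HU; Gaussian noise (default
SD 10 HU) is added after the truth is recorded.  What the phantom does
*not* model: beam hardening and streak artifacts, coronary vessels, cardiac
motion, anatomical shape variability beyond ellipsoids, and kV-dependent
fat attenuation shifts.  Passing phantom tests therefore demonstrates the
correctness of the pipeline's geometry, thresholding, statistics and
learning machinery — not clinical-grade segmentation of real anatomy.

`generate_dataset()` jitters heart size, fat fractions, core scale, noise
and wedge orientation, and rejection-samples specs so analytic EAT volumes
fall in 40–250 cm^3 (clinically realistic spread, mean ≈ 145 cm^3).

## Problem sizes and numerical choices

The validation suite runs the full system at reduced scale, chosen as the
smallest sizes at which every failure mode of interest is still expressed:

* geometry and threshold checks: 48^3 phantoms at 3 mm;
* volume recovery: 176^3 phantoms at 0.8 mm (supersample 4 noiseless,
  2 with noise);
* learning recovery: a 4-level UNet++ (channels 4, 8, 16, 32) on 64^3
  cubes at 2.5 mm, 20 training + 5 held-out phantoms, 12 epochs.  With
  ~240 optimizer steps instead of the many thousands of a clinical
  training run, the learning rate is raised to 1e−3 (RMSProp's
  normalized steps make this a step-count rescaling); the clinical recipe
  default of 1e−4 is retained in `train_config()`.  Held-out median
  pericardium Dice ≥ 0.85 and median relative EAT volume error ≤ 10% are
  reached for at least 2 of 3 seeds.

Other fixed numerical choices: inclusive HU window bounds on both ends;
threshold 0.5 on the sigmoid; instance-norm epsilon 1e−5; pixel-centre
alignment in all resampling; round-half-away-from-zero output shapes;
Dice of two empty masks defined as 1 (perfect agreement on "nothing");
ICC fixed to the two-way random-effects, absolute-agreement, single-measure
form ICC(2,1) with the standard F-based confidence interval — the
conventional choice for two-reader absolute-volume agreement;
Bland–Altman differences are predicted − reference, so underestimation
shows as negative bias.

## Contour interpolation

The manual annotation protocol delineates the pericardium on every 5th
axial slice (densified near the apex) and fills the rest by smooth
interpolation.  `interpolate_dense()` implements the standard shape-based
choice: per-slice signed Euclidean distance transforms of the two
bracketing annotations, blended linearly along z and thresholded at zero.
Annotated slices are reproduced exactly; for concentric disks the
interpolated radius grows linearly, which the tests verify against a
brute-force distance-transform oracle.  Equivalence with any particular
interactive tool's interpolation is not claimed.

## Known limitations

* DICOM support is deliberately minimal (single axial series, little-endian,
  16-bit, no tilt); convert anything else to NIfTI.
* The HU window is taken as given for 120 kV acquisitions; no kV
  recalibration, denoising, or metal-artifact handling is attempted.
* CPU-scale training cannot approach a clinically trained model; the
  network exists to validate the architecture and training recipe end to
  end, and as a faithful, reusable implementation for larger runs.
* Inter-machine bitwise reproducibility of training is not guaranteed
  (BLAS-dependent); within-machine runs are exactly reproducible by seed.
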