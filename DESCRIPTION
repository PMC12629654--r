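Package: eatct
Title: Automated Epicardial Adipose Tissue Volumetry from Non-Contrast Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Two-stage pipeline for fully automated quantification of
    epicardial adipose tissue (EAT) from non-contrast cardiac CT volumes:
    a 3D UNet++ voxel segmentation model localizes the pericardial sac,
    then Hounsfield-unit window thresholding (-190 to -30 HU) inside the
    predicted sac on the native-resolution image yields the EAT mask and
    volume.  Includes deterministic preprocessing (isotropic resampling,
    centred pad/crop to a fixed cube, intensity clipping and
    normalization, an auxiliary "redundant" fat-density training class
    for the inferior slices), shape-based interpolation of sparse
    per-slice pericardium contours, agreement statistics (Dice, relative
    volume error, Pearson, Bland-Altman, ICC(2,1)), and a synthetic
    thorax phantom generator with analytically known pericardium
    geometry and fat volume for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    withr,
    png,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
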