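#' Synthetic thorax phantom specification
#'
#' Defines a thorax-like non-contrast CT phantom: a soft-tissue body
#' ellipsoid with a subcutaneous fat layer, two lung ellipsoids, and a
#' closed ellipsoidal pericardial sac containing a heart core
#' (blood/myocardium), a thin pericardial line, and an epicardial fat
#' compartment of analytically known volume.  The fat compartment occupies
#' an angular wedge of the shell between the core and the sac; the wedge
#' fraction is `fat_fraction_equator` over most of the heart but
#' `fat_fraction_apex` in the inferior apex cap, reproducing the
#' inferior-heavy EAT distribution seen clinically.  Optional paracardial
#' fat (same HU, outside the sac) makes naive global thresholding fail.
#'
#' The wedge is defined in the normalized elliptic angle, in which area is
#' uniformly distributed, so the per-slice fat fraction of the shell equals
#' the wedge fraction exactly and the compartment volume has a closed form.
#'
#' @param shape native grid shape (3 ints).
#' @param spacing voxel spacing, mm.
#' @param heart_center sac centre in physical mm; default = grid centre.
#' @param heart_axes sac semi-axes (mm).
#' @param pericardium_thickness thickness of the rendered pericardial line
#'   (mm).
#' @param core_scale heart core semi-axes as a fraction of the sac's.
#' @param fat_fraction_equator,fat_fraction_apex wedge fractions of the
#'   fat shell away from / inside the apex cap (`apex >= equator`
#'   reproduces the inferior-heavy distribution).
#' @param apex_cap_fraction inferior fraction of the sac z-extent treated
#'   as the apex cap.
#' @param wedge_angle centre of the fat wedge (radians).
#' @param paracardial_fat render extra-pericardial fat (paracardial shell +
#'   subcutaneous layer)?
#' @param calcium_radius radius of a coronary-calcium surrogate sphere in
#'   the core (mm; 0 disables).
#' @param hu_means named HU means per material.
#' @param noise_sd additive Gaussian HU noise SD.
#' @param supersample sub-voxel sampling factor (>= 1) for partial-volume
#'   rendering.
#' @param seed RNG seed for the noise.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2.5, 2.5, 2.5),
                         heart_center = NULL,
                         heart_axes = c(50, 45, 52),
                         pericardium_thickness = 2.5,
                         core_scale = 0.72,
                         fat_fraction_equator = 0.4,
                         fat_fraction_apex = 0.95,
                         apex_cap_fraction = 0.22,
                         wedge_angle = 0.3,
                         paracardial_fat = TRUE,
                         calcium_radius = 5,
                         hu_means = c(air = -1000, soft = 40, lung = -800,
                                      fat = -100, line = 30, core = 45,
                                      calcium = 300),
                         noise_sd = 10,
                         supersample = 2L,
                         seed = 42L) {
  shape <- as.integer(shape); spacing <- as.numeric(spacing)
  extent <- shape * spacing
  if (is.null(heart_center)) heart_center <- extent / 2
  if (any(heart_center - heart_axes < 0) ||
      any(heart_center + heart_axes > extent))
    stop("spec error: heart ellipsoid exceeds the grid's physical extent")
  if (hu_means["fat"] <= -190 || hu_means["fat"] >= -30)
    stop("spec error: fat HU mean must lie in (-190, -30)")
  if (hu_means["fat"] <= -198 || hu_means["fat"] >= -80)
    stop("spec error: fat HU mean must overlap the redundant range (-198, -80)")
  if (fat_fraction_apex < fat_fraction_equator)
    stop("spec error: fat_fraction_apex must be >= fat_fraction_equator")
  if (min(fat_fraction_equator, fat_fraction_apex) < 0 ||
      max(fat_fraction_equator, fat_fraction_apex) > 1)
    stop("spec error: fat fractions must lie in [0, 1]")
  if (supersample < 1) stop("spec error: supersample must be >= 1")
  delta <- pericardium_thickness / mean(heart_axes)
  if (core_scale >= 1 - delta)
    stop("spec error: core_scale must leave room for the fat shell")
  structure(list(shape = shape, spacing = spacing,
                 heart_center = as.numeric(heart_center),
                 heart_axes = as.numeric(heart_axes),
                 pericardium_thickness = pericardium_thickness,
                 core_scale = core_scale,
                 fat_fraction_equator = fat_fraction_equator,
                 fat_fraction_apex = fat_fraction_apex,
                 apex_cap_fraction = apex_cap_fraction,
                 wedge_angle = wedge_angle,
                 paracardial_fat = isTRUE(paracardial_fat),
                 calcium_radius = calcium_radius,
                 hu_means = hu_means,
                 noise_sd = noise_sd,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# volume (mm^3) of the slab z in [z1,z2] of the sac ellipsoid scaled by s
ellipsoid_slab <- function(spec, s, z1, z2) {
  a <- s * spec$heart_axes[1]; b <- s * spec$heart_axes[2]
  c3 <- s * spec$heart_axes[3]; cz <- spec$heart_center[3]
  lo <- max(z1, cz - c3); hi <- min(z2, cz + c3)
  if (lo >= hi) return(0)
  antider <- function(z) {
    u <- (z - cz)
    u - u^3 / (3 * c3^2)
  }
  pi * a * b * (antider(hi) - antider(lo))
}

#' Analytic epicardial fat volume of a phantom (cm^3)
#'
#' Closed-form integral of the fat wedge over the shell between the heart
#' core and the inner surface of the pericardial line; independent of any
#' voxel rendering, so it serves as the ground-truth oracle for
#' convergence and recovery tests.
#'
#' @param spec a [phantom_spec()].
#' @return Fat compartment volume in cm^3.
#' @export
eat_volume_analytic <- function(spec) {
  delta <- spec$pericardium_thickness / mean(spec$heart_axes)
  cz <- spec$heart_center[3]; c3 <- spec$heart_axes[3]
  zlo <- cz - c3; zhi <- cz + c3
  zcap <- zlo + spec$apex_cap_fraction * 2 * c3
  shell <- function(z1, z2)
    ellipsoid_slab(spec, 1 - delta, z1, z2) -
      ellipsoid_slab(spec, spec$core_scale, z1, z2)
  (spec$fat_fraction_apex * shell(zlo, zcap) +
     spec$fat_fraction_equator * shell(zcap, zhi)) / 1000
}

phantom_params <- function(spec) {
  extent <- spec$shape * spec$spacing
  bcent <- extent / 2
  bax <- extent * c(0.48, 0.46, 0.75)
  delta <- spec$pericardium_thickness / mean(spec$heart_axes)
  hu <- spec$hu_means
  c(bcent, bax,
    spec$heart_center, spec$heart_axes,
    spec$core_scale, delta,
    spec$fat_fraction_equator, spec$fat_fraction_apex,
    spec$apex_cap_fraction, spec$wedge_angle,
    as.numeric(spec$paracardial_fat), 0.18,
    spec$heart_axes[1] + 22, 25, 0.36 * extent[2], 0.42 * extent[3],
    spec$calcium_radius, 0.10,
    hu["air"], hu["soft"], hu["lung"], hu["fat"], hu["line"], hu["core"],
    hu["calcium"],
    0.6)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Render a phantom volume and its ground truth
#'
#' Materials are rendered by supersampled sub-voxel occupancy, so boundary
#' voxels carry partial-volume-mixed HU; Gaussian noise is added after the
#' analytic truth is recorded.  Deterministic for a fixed spec.
#'
#' @param spec a [phantom_spec()].
#' @return `list(volume = ct_volume, truth = list(pericardium_mask,
#'   eat_mask, eat_volume_cm3, material_map), spec = spec)`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  r <- cpp_phantom_render(spec$shape, spec$spacing, phantom_params(spec),
                          spec$supersample)
  hu <- r$hu
  if (spec$noise_sd > 0)
    hu <- hu + with_seed(spec$seed, rnorm(length(hu), 0, spec$noise_sd))
  dim(hu) <- spec$shape
  peri <- array(as.double(r$sac_occ >= 0.5), spec$shape)
  fat <- array(as.double(r$fat_occ >= 0.5), spec$shape)
  mat <- array(r$material, spec$shape)
  vol <- ct_volume(hu, spec$spacing)
  truth <- list(pericardium_mask = seg_mask(peri, spec$spacing),
                eat_mask = seg_mask(fat, spec$spacing),
                eat_volume_cm3 = eat_volume_analytic(spec),
                material_map = mat)
  list(volume = vol, truth = truth, spec = spec)
}

#' Default jitter ranges for phantom datasets
#'
#' Each entry is a `c(lo, hi)` range sampled uniformly per case: a global
#' heart-size scale, per-axis centre shifts (mm), fat wedge fractions, core
#' scale, noise SD, and wedge angle.  `volume_range` (cm^3) is enforced by
#' rejection so generated EAT volumes mirror the clinical spread.
#'
#' @param axes_scale,center_shift_mm,fat_fraction_equator,fat_fraction_apex,core_scale,noise_sd,wedge_angle,volume_range
#'   ranges as described above.
#' @return A `phantom_jitter` list of ranges.
#' @export
phantom_jitter <- function(axes_scale = c(0.90, 1.18),
                           center_shift_mm = c(-6, 6),
                           fat_fraction_equator = c(0.30, 0.60),
                           fat_fraction_apex = c(0.80, 1.00),
                           core_scale = c(0.60, 0.78),
                           noise_sd = c(5, 15),
                           wedge_angle = c(-0.5, 0.5),
                           volume_range = c(40, 250)) {
  j <- list(axes_scale = axes_scale, center_shift_mm = center_shift_mm,
            fat_fraction_equator = fat_fraction_equator,
            fat_fraction_apex = fat_fraction_apex,
            core_scale = core_scale, noise_sd = noise_sd,
            wedge_angle = wedge_angle, volume_range = volume_range)
  for (nm in names(j)) {
    if (length(j[[nm]]) != 2L || j[[nm]][1] > j[[nm]][2])
      stop("spec error: jitter range '", nm, "' must be c(lo, hi) with lo <= hi")
  }
  structure(j, class = "phantom_jitter")
}

#' Generate a reproducible phantom dataset
#'
#' Draws per-case specs from the jitter ranges (rejection-sampled so the
#' analytic EAT volume falls inside `jitter$volume_range`) and renders each
#' phantom.  Fully reproducible for a fixed seed.
#'
#' @param n number of cases (>= 1).
#' @param base_spec base [phantom_spec()].
#' @param jitter a [phantom_jitter()].
#' @param seed integer seed.
#' @return List of `n` results as returned by [generate_phantom()].
#' @export
generate_dataset <- function(n, base_spec = phantom_spec(),
                             jitter = phantom_jitter(), seed = 1L) {
  stopifnot(n >= 1)
  specs <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in 1:100) {
        u <- function(r) runif(1, r[1], r[2])
        sc <- u(jitter$axes_scale)
        sp <- tryCatch(phantom_spec(
          shape = base_spec$shape, spacing = base_spec$spacing,
          heart_center = base_spec$heart_center %||%
            (base_spec$shape * base_spec$spacing / 2) +
            c(u(jitter$center_shift_mm), u(jitter$center_shift_mm),
              u(jitter$center_shift_mm)),
          heart_axes = base_spec$heart_axes * sc,
          pericardium_thickness = base_spec$pericardium_thickness,
          core_scale = u(jitter$core_scale),
          fat_fraction_equator = u(jitter$fat_fraction_equator),
          fat_fraction_apex = u(jitter$fat_fraction_apex),
          apex_cap_fraction = base_spec$apex_cap_fraction,
          wedge_angle = base_spec$wedge_angle + u(jitter$wedge_angle),
          paracardial_fat = base_spec$paracardial_fat,
          calcium_radius = base_spec$calcium_radius,
          hu_means = base_spec$hu_means,
          noise_sd = u(jitter$noise_sd),
          supersample = base_spec$supersample,
          seed = sample.int(.Machine$integer.max %/% 2, 1)),
          error = function(e) NULL)
        if (is.null(sp)) next
        v <- eat_volume_analytic(sp)
        if (v >= jitter$volume_range[1] && v <= jitter$volume_range[2])
          return(sp)
      }
      stop("spec error: could not draw a phantom inside volume_range")
    })
  })
  lapply(specs, generate_phantom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Down-sample a truth mask into a sparse every-k-th-slice annotation
#'
#' Emulates the manual annotation protocol: keep every `step`-th axial slice
#' of the dense pericardium mask over its non-empty extent, always including
#' the first and last non-empty slices.
#'
#' @param truth the `truth` element of [generate_phantom()].
#' @param step annotation stride in slices (default 5).
#' @return A [sparse_annotation()].
#' @export
sparse_annotation_from_truth <- function(truth, step = 5L) {
  m <- truth$pericardium_mask
  nz <- dim(m$data)[3]
  nonempty <- which(apply(m$data, 3, sum) > 0)
  if (length(nonempty) == 0L)
    stop("sparse_annotation_from_truth: truth mask is empty")
  z1 <- min(nonempty); z2 <- max(nonempty)
  idx <- sort(unique(c(seq(z1, z2, by = step), z1, z2)))
  slices <- stats::setNames(lapply(idx, function(z) m$data[, , z]),
                            as.character(idx))
  sparse_annotation(slices, dim(m$data), m$spacing, bounds = c(z1, z2))
}
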