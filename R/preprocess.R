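#' Preprocessing configuration
#'
#' Bundles the deterministic preprocessing parameters used to turn a native
#' CT volume into the fixed-size normalized training cube: isotropic target
#' spacing (mm), cube edge length (voxels), the HU clipping window applied
#' before [0,1] normalization, the HU window defining the auxiliary
#' "redundant" fat-density class, and the inferior fraction of axial slices
#' that class is restricted to.
#'
#' @param target_spacing_mm isotropic resample spacing, mm (default 1.6).
#' @param cube_size output cube edge, voxels (default 128).
#' @param clip_lo_hu,clip_hi_hu intensity clipping window (default -800, 1200).
#' @param redundant_lo_hu,redundant_hi_hu HU window of the redundant class
#'   (default -198, -80).
#' @param inferior_fraction fraction of the most-inferior axial slices in
#'   which the redundant class may occur (default 0.2).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_spacing_mm = 1.6, cube_size = 128L,
                              clip_lo_hu = -800, clip_hi_hu = 1200,
                              redundant_lo_hu = -198, redundant_hi_hu = -80,
                              inferior_fraction = 0.2) {
  if (target_spacing_mm <= 0) stop("parameter error: target_spacing_mm <= 0")
  if (clip_lo_hu >= clip_hi_hu) stop("parameter error: clip_lo_hu >= clip_hi_hu")
  if (redundant_lo_hu >= redundant_hi_hu)
    stop("parameter error: redundant_lo_hu >= redundant_hi_hu")
  if (inferior_fraction <= 0 || inferior_fraction >= 1)
    stop("parameter error: inferior_fraction must lie in (0,1)")
  structure(list(target_spacing_mm = target_spacing_mm,
                 cube_size = as.integer(cube_size),
                 clip_lo_hu = clip_lo_hu, clip_hi_hu = clip_hi_hu,
                 redundant_lo_hu = redundant_lo_hu,
                 redundant_hi_hu = redundant_hi_hu,
                 inferior_fraction = inferior_fraction),
            class = "preprocess_config")
}

#' Resample a volume to isotropic spacing
#'
#' Output shape per axis is `round(n * spacing / target)` (half away from
#' zero, minimum 1).  Trilinear interpolation is used for images, nearest
#' neighbour for masks/labels (so 0/1 inputs stay 0/1).  Sampling uses voxel
#' centre alignment, so physical extents are preserved.
#'
#' @param vol a canonical [ct_volume()], [seg_mask()] or label volume.
#' @param target_spacing isotropic target spacing in mm (> 0).
#' @param mode `"trilinear"` or `"nearest"`.
#' @return The resampled object (class preserved).
#' @export
resample_isotropic <- function(vol, target_spacing,
                               mode = c("trilinear", "nearest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target_spacing) || target_spacing <= 0)
    stop("parameter error: target_spacing must be > 0")
  n <- dim(vol$data)
  out_n <- pmax(1L, as.integer(floor(n * vol$spacing / target_spacing + 0.5)))
  scale <- target_spacing / vol$spacing
  d <- cpp_resample(as.double(vol$data), as.integer(n), out_n, scale,
                    mode == "nearest")
  dim(d) <- out_n
  out <- vol
  out$data <- d
  out$spacing <- rep(target_spacing, 3)
  # voxel-centre alignment shifts the first voxel centre by (t - s)/2
  out$origin <- vol$origin + (target_spacing - vol$spacing) / 2
  out
}

#' Pad and/or crop a volume symmetrically to a cube
#'
#' Pads (value `pad_value`) and/or crops each axis to length `cube_size`,
#' splitting the difference as evenly as possible (low side gets the smaller
#' half).  Returns the cube together with a `grid_transform` record that
#' exactly describes the operation, so it can be inverted later.
#'
#' @param vol a [ct_volume()]-like object.
#' @param cube_size target edge length (voxels).
#' @param pad_value fill value for padded voxels (use the clip floor HU for
#'   images, 0 for masks/labels).
#' @return `list(volume =, transform =)`.
#' @export
pad_crop_center <- function(vol, cube_size, pad_value = 0) {
  n <- dim(vol$data)
  cube <- as.integer(cube_size)
  pad_low <- pad_high <- crop_low <- crop_high <- integer(3)
  for (k in 1:3) {
    if (n[k] < cube) {
      p <- cube - n[k]
      pad_low[k] <- p %/% 2L; pad_high[k] <- p - pad_low[k]
    } else if (n[k] > cube) {
      cdiff <- n[k] - cube
      crop_low[k] <- cdiff %/% 2L; crop_high[k] <- cdiff - crop_low[k]
    }
  }
  d <- array(pad_value, rep(cube, 3))
  src <- lapply(1:3, function(k) seq.int(1L + crop_low[k], n[k] - crop_high[k]))
  dst <- lapply(1:3, function(k) seq.int(1L + pad_low[k],
                                         pad_low[k] + length(src[[k]])))
  d[dst[[1]], dst[[2]], dst[[3]]] <-
    vol$data[src[[1]], src[[2]], src[[3]], drop = FALSE]
  out <- vol
  out$data <- d
  tr <- structure(list(native_shape = NULL, native_spacing = NULL,
                       target_spacing = vol$spacing[1],
                       resampled_shape = n, cube_size = cube,
                       pad_low = pad_low, pad_high = pad_high,
                       crop_low = crop_low, crop_high = crop_high),
                  class = "grid_transform")
  list(volume = out, transform = tr)
}

#' Clip intensities and normalize to [0, 1]
#'
#' Applies `(clamp(x, lo, hi) - lo) / (hi - lo)` voxelwise.
#'
#' @param vol a [ct_volume()].
#' @param lo,hi clipping window in HU; `lo < hi`.
#' @return The volume with unitless data in `[0, 1]`.
#' @export
clip_normalize <- function(vol, lo = -800, hi = 1200) {
  if (lo >= hi) stop("parameter error: lo >= hi")
  out <- vol
  out$data <- (pmin(pmax(vol$data, lo), hi) - lo) / (hi - lo)
  out
}

#' Build the three-class training label volume
#'
#' Label 1 marks the pericardium.  Label 2 ("redundant") marks fat-density
#' voxels (`redundant_lo_hu..redundant_hi_hu`) *outside* the pericardium in
#' the most-inferior `ceil(inferior_fraction * nz)` axial slices; it gives
#' the network an explicit target for the ambiguous fat just below/around
#' the cardiac apex.  The pericardium takes precedence, so labels 1 and 2
#' are disjoint by construction.  All other voxels are background (0).
#'
#' @param vol HU volume (canonical orientation).
#' @param pericardium paired [seg_mask()] on the same grid.
#' @param cfg a [preprocess_config()].
#' @return A `ct_volume` whose data contains labels in `{0, 1, 2}`.
#' @export
make_redundant_class <- function(vol, pericardium, cfg = preprocess_config()) {
  check_same_grid(vol, pericardium, "volume and pericardium mask")
  n <- dim(vol$data)
  zmax <- as.integer(ceiling(cfg$inferior_fraction * n[3]))  # slices 1..zmax
  lab <- array(0, n)
  lab[pericardium$data == 1] <- 1
  if (zmax >= 1L) {
    zidx <- seq_len(min(zmax, n[3]))
    sub <- vol$data[, , zidx, drop = FALSE]
    red <- (sub >= cfg$redundant_lo_hu) & (sub <= cfg$redundant_hi_hu) &
      (pericardium$data[, , zidx, drop = FALSE] == 0)
    labsub <- lab[, , zidx, drop = FALSE]
    labsub[red] <- 2
    lab[, , zidx] <- labsub
  }
  out <- vol
  out$data <- lab
  class(out) <- "ct_volume"
  out
}

#' Run the full preprocessing pipeline
#'
#' resample (trilinear image / nearest mask) -> centred pad/crop to the cube
#' -> clip + normalize (image only).  The redundant-class labels are
#' computed on the resampled HU grid, before normalization, so supervision
#' and input share one grid.  The returned `grid_transform` is sufficient to
#' map a cube-grid prediction back to the native grid with
#' [invert_to_native()].
#'
#' @param vol native-grid HU [ct_volume()] (any orientation; canonicalized).
#' @param pericardium optional paired [seg_mask()].
#' @param cfg a [preprocess_config()].
#' @return `list(image = cube array in [0,1], labels = cube array over
#'   {0,1,2} or NULL, transform = grid_transform)`.
#' @export
apply_pipeline <- function(vol, pericardium = NULL, cfg = preprocess_config()) {
  vol <- canonicalize(vol)
  native_shape <- dim(vol$data); native_spacing <- vol$spacing
  r <- resample_isotropic(vol, cfg$target_spacing_mm, "trilinear")
  pc <- pad_crop_center(r, cfg$cube_size, pad_value = cfg$clip_lo_hu)
  img <- clip_normalize(pc$volume, cfg$clip_lo_hu, cfg$clip_hi_hu)
  tr <- pc$transform
  tr$native_shape <- native_shape
  tr$native_spacing <- native_spacing
  tr$target_spacing <- cfg$target_spacing_mm
  labels <- NULL
  if (!is.null(pericardium)) {
    pericardium <- canonicalize(pericardium)
    check_same_grid(vol, pericardium, "volume and pericardium mask")
    rm <- resample_isotropic(pericardium, cfg$target_spacing_mm, "nearest")
    lab <- make_redundant_class(r, seg_mask(rm$data, rm$spacing, rm$origin,
                                            rm$axcodes), cfg)
    labels <- pad_crop_center(lab, cfg$cube_size, pad_value = 0)$volume$data
  }
  list(image = img$data, labels = labels, transform = tr)
}

#' Map a cube-grid binary mask back to the native grid
#'
#' Inverts [apply_pipeline()]'s geometry: removes the padding, restores the
#' cropped margins (zero-filled), and nearest-neighbour resamples from the
#' isotropic grid back to the native spacing and shape.
#'
#' @param mask_cube binary array of shape `cube^3` (or a [seg_mask()]).
#' @param transform the `grid_transform` produced by [apply_pipeline()].
#' @param native the native-grid [ct_volume()] the transform came from.
#' @return A [seg_mask()] on the native grid.
#' @export
invert_to_native <- function(mask_cube, transform, native) {
  m <- if (inherits(mask_cube, "ct_volume")) mask_cube$data else mask_cube
  cube <- transform$cube_size
  if (!identical(dim(m), rep(cube, 3L)) && !identical(dim(m), as.integer(rep(cube, 3))))
    stop("alignment error: mask shape ", paste(dim(m), collapse = "x"),
         " does not match transform cube size ", cube)
  native <- canonicalize(native)
  if (!identical(dim(native$data), as.integer(transform$native_shape)) &&
      !identical(dim(native$data), transform$native_shape))
    stop("alignment error: native volume shape does not match transform")
  # un-pad
  keep <- lapply(1:3, function(k)
    seq.int(1L + transform$pad_low[k], cube - transform$pad_high[k]))
  inner <- m[keep[[1]], keep[[2]], keep[[3]], drop = FALSE]
  # un-crop (zero fill)
  rs <- transform$resampled_shape
  full <- array(0, rs)
  dst <- lapply(1:3, function(k)
    seq.int(1L + transform$crop_low[k], rs[k] - transform$crop_high[k]))
  full[dst[[1]], dst[[2]], dst[[3]]] <- inner
  # nearest-neighbour back to the native grid
  scale <- transform$native_spacing / transform$target_spacing
  d <- cpp_resample(as.double(full), as.integer(rs),
                    as.integer(transform$native_shape), scale, TRUE)
  dim(d) <- transform$native_shape
  seg_mask(round(d), native$spacing, native$origin, native$axcodes)
}
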