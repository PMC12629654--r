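#' Adipose-tissue HU window
#'
#' The established CT attenuation range for adipose tissue at 120 kV,
#' -190..-30 HU.  Bounds are inclusive on both ends.
#'
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return An `eat_window` list.
#' @export
eat_window <- function(lo = -190, hi = -30) {
  if (lo >= hi) stop("parameter error: lo >= hi")
  structure(list(lo = lo, hi = hi), class = "eat_window")
}

#' Extract the EAT mask and volume inside the pericardium
#'
#' Stage two of the pipeline: on the native-resolution HU image, a voxel is
#' epicardial adipose tissue iff it lies inside the pericardium mask and its
#' HU falls in the adipose window (inclusive bounds).  The volume is the
#' voxel count times the voxel volume; the per-slice profile (inferior
#' first) supports regional analyses.
#'
#' @param vol native-grid HU [ct_volume()], canonical orientation.
#' @param pericardium paired [seg_mask()] (manual or predicted).
#' @param window an [eat_window()].
#' @return An `eat_result` with fields `mask` ([seg_mask()]), `volume_cm3`,
#'   `n_voxels`, `window`, `spacing`, and `slice_profile` (cm^3 per axial
#'   slice, inferior first).
#' @export
extract_eat <- function(vol, pericardium, window = eat_window()) {
  stopifnot(inherits(vol, "ct_volume"), inherits(pericardium, "ct_volume"))
  check_same_grid(vol, pericardium, "volume and pericardium mask")
  m <- (pericardium$data == 1) & (vol$data >= window$lo) &
    (vol$data <= window$hi)
  storage.mode(m) <- "double"
  voxvol_cm3 <- prod(vol$spacing) / 1000
  nvox <- sum(m)
  profile <- apply(m, 3, sum) * voxvol_cm3
  structure(list(mask = seg_mask(m, vol$spacing, vol$origin, vol$axcodes),
                 volume_cm3 = nvox * voxvol_cm3,
                 n_voxels = nvox,
                 window = window,
                 spacing = vol$spacing,
                 slice_profile = profile),
            class = "eat_result")
}

#' @export
print.eat_result <- function(x, ...) {
  cat(sprintf("EAT: %.2f cm^3 (%d voxels, window [%g, %g] HU, spacing %s mm)\n",
              x$volume_cm3, x$n_voxels, x$window$lo, x$window$hi,
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Share of EAT volume in the most-inferior slices
#'
#' Over the axial slices that contain any EAT, returns the fraction of the
#' total EAT volume held by the most-inferior `ceil(fraction * n)` of them.
#' This quantifies the apex-region dominance of the EAT distribution (the
#' inferior 15-20% of EAT slices typically hold over 20% of the volume),
#' which motivates the redundant-class supervision.
#'
#' @param result an [extract_eat()] result.
#' @param fraction fraction of EAT-containing slices to count, in (0, 1).
#' @return Proportion in `[0, 1]`.
#' @export
inferior_share <- function(result, fraction = 0.2) {
  stopifnot(inherits(result, "eat_result"))
  if (fraction <= 0 || fraction >= 1)
    stop("parameter error: fraction must lie in (0,1)")
  total <- sum(result$slice_profile)
  if (total <= 0)
    stop("undefined share: total EAT volume is zero")
  eat_slices <- which(result$slice_profile > 0)
  k <- ceiling(fraction * length(eat_slices))
  sum(result$slice_profile[eat_slices[seq_len(k)]]) / total
}
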