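#' CT volume container
#'
#' A 3D scalar grid of Hounsfield units together with the geometric metadata
#' needed to interpret it: per-axis voxel spacing in millimetres, the world
#' coordinate of the first voxel centre, and anatomical axis codes.  Axis
#' codes use the radiological single-letter convention giving the anatomical
#' direction in which the voxel index *increases*: `R`/`L` (right/left),
#' `A`/`P` (anterior/posterior), `S`/`I` (superior/inferior).  The canonical
#' orientation used throughout the package is `c("R","A","S")`, so that axial
#' slice index 1 is the most *inferior* slice.
#'
#' @param data 3D numeric array of intensities (HU for images).
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, world (R,A,S) coordinate of voxel (1,1,1).
#' @param axcodes character length-3 of axis codes as described above.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0),
                      axcodes = c("R", "A", "S")) {
  if (length(dim(data)) != 3L)
    stop("ct_volume: `data` must have exactly 3 axes, got ",
         length(dim(data)))
  if (any(dim(data) < 1L)) stop("ct_volume: every axis must have length >= 1")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("ct_volume: `spacing` must be 3 strictly positive finite values")
  axcodes <- validate_axcodes(axcodes)
  structure(list(data = if (is.double(data)) data else array(as.double(data), dim(data)),
                 spacing = spacing,
                 origin = as.numeric(origin),
                 axcodes = axcodes),
            class = "ct_volume")
}

#' Binary segmentation mask on a CT grid
#'
#' A `seg_mask` shares the grid (shape, spacing, origin, orientation) of its
#' paired [ct_volume()] and holds only values 0/1.
#'
#' @inheritParams ct_volume
#' @return An object of class `c("seg_mask", "ct_volume")`.
#' @export
seg_mask <- function(data, spacing, origin = c(0, 0, 0),
                     axcodes = c("R", "A", "S")) {
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("seg_mask: data values must be 0/1; found ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "))
  v <- ct_volume(data, spacing, origin, axcodes)
  class(v) <- c("seg_mask", "ct_volume")
  v
}

# axis code -> (world axis 1..3, sign of increasing index)
axcode_table <- function() {
  list(R = c(1L, 1L), L = c(1L, -1L),
       A = c(2L, 1L), P = c(2L, -1L),
       S = c(3L, 1L), I = c(3L, -1L))
}

validate_axcodes <- function(axcodes) {
  axcodes <- toupper(as.character(axcodes))
  tab <- axcode_table()
  if (length(axcodes) != 3L || !all(axcodes %in% names(tab)))
    stop("unresolvable orientation metadata: axis codes must be three of ",
         "R/L/A/P/S/I, got ", paste(axcodes, collapse = ","))
  world <- vapply(axcodes, function(a) tab[[a]][1L], integer(1))
  if (length(unique(world)) != 3L)
    stop("unresolvable orientation metadata: axis codes ",
         paste(axcodes, collapse = ","), " do not span the three ",
         "anatomical axes")
  axcodes
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm, orientation %s\n",
              class(x)[1L], paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(x$axcodes, collapse = "")))
  cat(sprintf("  intensity range [%.6g, %.6g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

is_canonical <- function(vol) identical(vol$axcodes, c("R", "A", "S"))

#' Reorient a volume to the canonical RAS convention
#'
#' Permutes and flips the data axes so that increasing indices run toward the
#' patient's Right / Anterior / Superior.  In particular axis 3 becomes
#' the inferior-to-superior axis with slice index 1 most inferior, which is
#' the convention every "inferior fraction" rule in this package is defined
#' against.  Voxel values are untouched (the multiset of intensities is
#' preserved); spacing and origin are permuted/adjusted consistently.
#' Idempotent.
#'
#' @param vol a [ct_volume()] or [seg_mask()].
#' @return The reoriented object, with `axcodes = c("R","A","S")`.
#' @export
canonicalize <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  axcodes <- validate_axcodes(vol$axcodes)
  if (identical(axcodes, c("R", "A", "S"))) return(vol)
  tab <- axcode_table()
  world <- vapply(axcodes, function(a) tab[[a]][1L], integer(1))
  sign  <- vapply(axcodes, function(a) tab[[a]][2L], integer(1))
  perm <- match(1:3, world)            # data axis that realises world axis w
  d <- aperm(vol$data, perm)
  spacing <- vol$spacing[perm]
  sign <- sign[perm]
  origin <- vol$origin
  n <- dim(d)
  for (w in 1:3) {
    if (sign[w] < 0) {
      idx <- list(seq_len(n[1]), seq_len(n[2]), seq_len(n[3]))
      idx[[w]] <- rev(idx[[w]])
      d <- do.call(`[`, c(list(d), idx, list(drop = FALSE)))
      # first voxel is now what used to be the last along this axis
      origin[w] <- origin[w] - (n[w] - 1) * spacing[w]
    }
  }
  out <- vol
  out$data <- d
  out$spacing <- spacing
  out$origin <- origin
  out$axcodes <- c("R", "A", "S")
  out
}

# shared-grid check used across modules
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$data), dim(b$data)))
    stop("alignment error: ", what, " have different shapes (",
         paste(dim(a$data), collapse = "x"), " vs ",
         paste(dim(b$data), collapse = "x"), ")")
  if (max(abs(a$spacing - b$spacing)) > 1e-6)
    stop("alignment error: ", what, " have different voxel spacing")
  invisible(TRUE)
}
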