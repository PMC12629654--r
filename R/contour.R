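#' Sparse per-slice pericardium annotation
#'
#' Represents the manual annotation workflow in which the pericardium is
#' delineated on a subset of axial slices (classically every 5th, densified
#' near the apex) and the remaining slices are filled in by shape-based
#' interpolation.  Slice indices refer to the canonical inferior-first axial
#' axis.
#'
#' @param slices named list of 2D binary matrices; names are the (1-based)
#'   slice indices they annotate.  All matrices must share one shape.
#' @param shape length-3 integer grid shape of the parent volume.
#' @param spacing voxel spacing in mm of the parent volume.
#' @param bounds optional `c(inferior_idx, superior_idx)` of the annotated
#'   heart extent; defaults to the range of annotated slice indices.  Slices
#'   outside the bounds are left empty by [interpolate_dense()].
#' @return A `sparse_annotation` object.
#' @export
sparse_annotation <- function(slices, shape, spacing = c(1, 1, 1),
                              bounds = NULL) {
  idx <- as.integer(names(slices))
  if (length(idx) == 0L || any(is.na(idx)))
    stop("sparse_annotation: `slices` must be a named list keyed by slice index")
  dims <- unique(lapply(slices, dim))
  if (length(dims) != 1L)
    stop("sparse_annotation: all annotated slices must share one shape")
  if (!identical(as.integer(dims[[1]]), as.integer(shape[1:2])))
    stop("sparse_annotation: slice shape does not match the volume grid")
  if (any(idx < 1L | idx > shape[3]))
    stop("sparse_annotation: slice index out of range")
  if (is.null(bounds)) bounds <- range(idx)
  if (bounds[1] > min(idx) || bounds[2] < max(idx))
    stop("sparse_annotation: bounds must contain every annotated slice")
  ord <- order(idx)
  structure(list(slices = lapply(slices[ord], function(m) (m != 0) * 1),
                 idx = idx[ord], shape = as.integer(shape),
                 spacing = as.numeric(spacing),
                 bounds = as.integer(bounds)),
            class = "sparse_annotation")
}

# signed Euclidean distance of a binary 2D mask: positive inside, negative
# outside (EBImage::distmap gives the distance-to-background of foreground
# pixels).  Degenerate all-0 / all-1 slices get a large constant of the
# matching sign.
signed_distance_2d <- function(m) {
  big <- sum(dim(m))
  if (all(m == 0)) return(matrix(-big, nrow(m), ncol(m)))
  if (all(m == 1)) return(matrix(big, nrow(m), ncol(m)))
  inside <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
  outside <- as.matrix(EBImage::distmap(1 - m, metric = "euclidean"))
  inside - outside
}

#' Interpolate a dense pericardium mask from sparse slice annotations
#'
#' Annotated slices are reproduced exactly.  Each unannotated slice between
#' two annotated neighbours is filled by shape-based interpolation: the
#' per-slice signed Euclidean distance transforms of the two neighbours are
#' blended linearly along z and thresholded at zero.  Slices outside the
#' annotation bounds stay empty.
#'
#' @param ann a [sparse_annotation()].
#' @return A [seg_mask()] of the annotated volume's shape.
#' @export
interpolate_dense <- function(ann) {
  stopifnot(inherits(ann, "sparse_annotation"))
  if (length(ann$idx) < 2L)
    stop("insufficient annotation: need at least 2 annotated slices, got ",
         length(ann$idx))
  out <- array(0, ann$shape)
  for (i in seq_along(ann$idx)) out[, , ann$idx[i]] <- ann$slices[[i]]
  for (i in seq_len(length(ann$idx) - 1L)) {
    z1 <- ann$idx[i]; z2 <- ann$idx[i + 1L]
    if (z2 - z1 < 2L) next
    sd1 <- signed_distance_2d(ann$slices[[i]])
    sd2 <- signed_distance_2d(ann$slices[[i + 1L]])
    for (z in seq.int(z1 + 1L, z2 - 1L)) {
      w <- (z - z1) / (z2 - z1)
      out[, , z] <- (((1 - w) * sd1 + w * sd2) > 0) * 1
    }
  }
  seg_mask(out, ann$spacing)
}

#' Read a sparse annotation stored as a NIfTI label map
#'
#' Unannotated slices carry the sentinel value 255 everywhere; annotated
#' slices carry 0/1.
#'
#' @param path NIfTI file path.
#' @param bounds optional explicit annotation bounds (slice indices).
#' @return A [sparse_annotation()].
#' @export
read_sparse_annotation <- function(path, bounds = NULL) {
  vol <- read_volume(path)
  nz <- dim(vol$data)[3]
  ann <- list()
  for (z in seq_len(nz)) {
    sl <- vol$data[, , z]
    if (!all(sl == 255)) ann[[as.character(z)]] <- (sl != 0 & sl != 255) * 1
  }
  sparse_annotation(ann, dim(vol$data), vol$spacing, bounds)
}

#' Read a sparse annotation from a per-slice PNG stack
#'
#' The directory must contain an `index.json` of the form
#' `{"shape": [nx, ny, nz], "spacing": [sx, sy, sz],
#'   "slices": {"<z>": "file.png", ...}}`; each PNG holds one annotated
#' axial slice (non-zero = pericardium).
#'
#' @param dir directory containing `index.json` and the PNG files.
#' @param bounds optional explicit annotation bounds (slice indices).
#' @return A [sparse_annotation()].
#' @export
read_sparse_annotation_png <- function(dir, bounds = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read PNG annotation stacks")
  idx_file <- file.path(dir, "index.json")
  if (!file.exists(idx_file))
    stop("I/O error: '", idx_file, "' not found")
  idx <- jsonlite::read_json(idx_file, simplifyVector = TRUE)
  slices <- lapply(idx$slices, function(f) {
    m <- png::readPNG(file.path(dir, f))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    # PNG rows run top-down; transpose back to (x, y) voxel order
    (t(m)[, rev(seq_len(nrow(m)))] != 0) * 1
  })
  sparse_annotation(slices, idx$shape, idx$spacing %||% c(1, 1, 1), bounds)
}

#' Write a sparse annotation as a NIfTI label map (sentinel 255)
#'
#' @param ann a [sparse_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sparse_annotation <- function(ann, path) {
  d <- array(255, ann$shape)
  for (i in seq_along(ann$idx)) d[, , ann$idx[i]] <- ann$slices[[i]]
  write_volume(ct_volume(d, ann$spacing), path)
  invisible(path)
}
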