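#' Read a CT volume from NIfTI or a DICOM series
#'
#' NIfTI-1/NIfTI-2 files are read with RNifti; intensities are returned with
#' the header's scale slope/intercept already applied (HU for CT).  If `path`
#' is a directory it is treated as a single axial DICOM series (see
#' [read_dicom_series()]).  The returned volume is always in the canonical
#' RAS orientation (see [canonicalize()]).
#'
#' @param path path to a `.nii`/`.nii.gz` file or a DICOM series directory.
#' @param mask logical; if `TRUE` the result is validated and returned as a
#'   [seg_mask()].
#' @return A [ct_volume()] (or [seg_mask()]).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path))
    stop("I/O error: cannot read '", path, "' (no such file or directory)")
  if (dir.exists(path)) {
    vol <- read_dicom_series(path)
  } else {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e)
                      stop("I/O error reading '", path, "': ",
                           conditionMessage(e)))
    dm <- dim(img)
    if (length(dm) == 4L && dm[4] == 1L) {
      img2 <- array(as.double(img), dm)[, , , 1, drop = FALSE]
      dim(img2) <- dm[1:3]
    } else if (length(dm) == 3L) {
      img2 <- array(as.double(img), dm)
    } else {
      stop("shape error: '", path, "' is not a 3D image (dim ",
           paste(dm, collapse = "x"), ")")
    }
    pd <- RNifti::pixdim(img)[1:3]
    if (any(!is.finite(pd)) || any(pd <= 0))
      stop("metadata error: '", path, "' has invalid voxel spacing")
    axcodes <- strsplit(RNifti::orientation(img), "")[[1]]
    origin <- RNifti::xform(img)[1:3, 4]
    vol <- ct_volume(img2, spacing = pd, origin = origin, axcodes = axcodes)
  }
  vol <- canonicalize(vol)
  if (mask) {
    vol <- seg_mask(round(vol$data), vol$spacing, vol$origin, vol$axcodes)
  }
  vol
}

#' Write a CT volume or mask to NIfTI-1
#'
#' Masks are stored as unsigned 8-bit; images as signed 16-bit when all
#' values are 16-bit integers and as 32-bit float otherwise.  The affine is
#' rebuilt from spacing, origin and axis codes, so a written file
#' round-trips through [read_volume()] unchanged.
#'
#' @param vol a [ct_volume()] or [seg_mask()].
#' @param path output file path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!dir.exists(dirname(path)))
    stop("I/O error: directory '", dirname(path), "' does not exist")
  tab <- axcode_table()
  aff <- matrix(0, 4, 4); aff[4, 4] <- 1
  for (k in 1:3) {
    ws <- tab[[vol$axcodes[k]]]
    aff[ws[1L], k] <- ws[2L] * vol$spacing[k]
  }
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  datatype <- if (inherits(vol, "seg_mask")) {
    "uint8"
  } else {
    v <- vol$data
    if (all(v == round(v)) && min(v) >= -32768 && max(v) <= 32767)
      "int16" else "float"
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
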