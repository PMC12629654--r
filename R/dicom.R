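# Minimal DICOM single-series reader.
#
# Scope (deliberate): single-frame, axially acquired CT series with
# little-endian transfer syntax (explicit or implicit VR), monotone slice
# positions, no gantry tilt, uncompressed 16-bit pixel data.  Anything else
# must be converted to NIfTI first.  RescaleSlope/RescaleIntercept are
# honoured so returned intensities are HU.

dcm_uint <- function(raw, from, n) {
  v <- 0
  for (i in seq_len(n)) v <- v + as.integer(raw[from + i - 1L]) * 256^(i - 1)
  v
}

# parse one little-endian dataset (vector of raw) into a tag->raw-value list
dcm_parse_dataset <- function(raw, explicit) {
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  out <- list()
  pos <- 1L
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- dcm_uint(raw, pos, 2L); elem <- dcm_uint(raw, pos + 2L, 2L)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% long_vrs) {
        len <- dcm_uint(raw, pos + 4L, 4L); pos <- pos + 8L
      } else {
        len <- dcm_uint(raw, pos + 2L, 2L); pos <- pos + 4L
      }
    } else {
      vr <- ""
      len <- dcm_uint(raw, pos, 4L); pos <- pos + 4L
    }
    if (len == 4294967295) # undefined length (sequences): unsupported
      stop("metadata error: undefined-length DICOM element (",
           sprintf("%04x,%04x", group, elem), ") is not supported")
    key <- sprintf("%04x%04x", group, elem)
    out[[key]] <- raw[seq.int(pos, length.out = len)]
    pos <- pos + len
  }
  out
}

dcm_str <- function(el) if (is.null(el)) NULL else
  trimws(rawToChar(el[el != as.raw(0)]))
dcm_nums <- function(el) if (is.null(el)) NULL else
  as.numeric(strsplit(dcm_str(el), "\\\\")[[1]])

dcm_read_file <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 136L || rawToChar(raw[129:132]) != "DICM")
    stop("I/O error: '", path, "' is not a DICOM part-10 file")
  # file meta group is always explicit VR little endian
  pos <- 133L
  meta_len <- NULL
  ts <- "1.2.840.10008.1.2.1"
  # read (0002,0000) group length first
  repeat {
    group <- dcm_uint(raw, pos, 2L); elem <- dcm_uint(raw, pos + 2L, 2L)
    if (group != 2L) break
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- dcm_uint(raw, pos + 8L, 4L); hdr <- 12L
    } else {
      len <- dcm_uint(raw, pos + 6L, 2L); hdr <- 8L
    }
    val <- raw[seq.int(pos + hdr, length.out = len)]
    if (group == 2L && elem == 16L) ts <- trimws(rawToChar(val[val != as.raw(0)]))
    pos <- pos + hdr + len
    if (pos > length(raw)) break
  }
  explicit <- ts != "1.2.840.10008.1.2"
  if (!(ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
    stop("metadata error: unsupported DICOM transfer syntax ", ts)
  dcm_parse_dataset(raw[pos:length(raw)], explicit)
}

#' Read an axial DICOM series as a CT volume
#'
#' Reads every file in `dir`, sorts slices by the z component of
#' ImagePositionPatient (falling back to SliceLocation), applies
#' RescaleSlope/RescaleIntercept to obtain HU, and assembles a canonical
#' [ct_volume()].  Only identity in-plane orientation (no gantry tilt,
#' `ImageOrientationPatient = 1\\0\\0\\0\\1\\0`) is supported.
#'
#' @param dir directory containing exactly one single-frame CT series.
#' @return A [ct_volume()] in canonical orientation.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L)
    stop("I/O error: no files in DICOM directory '", dir, "'")
  slices <- lapply(files, dcm_read_file)
  zs <- vapply(slices, function(s) {
    ipp <- dcm_nums(s[["00200032"]])
    if (!is.null(ipp) && length(ipp) == 3L) return(ipp[3])
    sl <- dcm_nums(s[["00201041"]])
    if (!is.null(sl)) return(sl[1])
    stop("metadata error: DICOM slice lacks ImagePositionPatient/SliceLocation")
  }, numeric(1))
  ord <- order(zs)
  slices <- slices[ord]; zs <- zs[ord]
  s1 <- slices[[1L]]
  iop <- dcm_nums(s1[["00200037"]])
  if (!is.null(iop) && max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-3)
    stop("metadata error: non-axial DICOM orientation is not supported")
  rows <- dcm_uint(s1[["00280010"]], 1L, 2L)
  cols <- dcm_uint(s1[["00280011"]], 1L, 2L)
  ps <- dcm_nums(s1[["00280030"]])
  if (is.null(ps)) stop("metadata error: DICOM series lacks PixelSpacing")
  dz <- if (length(zs) > 1L) diff(zs) else dcm_nums(s1[["00180050"]])
  if (is.null(dz)) stop("metadata error: cannot determine slice spacing")
  if (length(zs) > 1L && (any(dz <= 0) || diff(range(dz)) > 1e-3))
    stop("metadata error: DICOM slice locations are not uniformly increasing")
  bits <- dcm_uint(s1[["00280100"]], 1L, 2L)
  if (bits != 16L)
    stop("metadata error: only 16-bit DICOM pixel data is supported")
  pixrep <- if (!is.null(s1[["00280103"]])) dcm_uint(s1[["00280103"]], 1L, 2L) else 0L
  data <- array(0, c(cols, rows, length(slices)))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    px <- s[["7fe00010"]]
    if (is.null(px)) stop("corrupt DICOM file: missing pixel data")
    v <- readBin(px, "integer", n = rows * cols, size = 2L,
                 signed = pixrep == 1L, endian = "little")
    slope <- dcm_nums(s[["00281053"]]); if (is.null(slope)) slope <- 1
    inter <- dcm_nums(s[["00281052"]]); if (is.null(inter)) inter <- 0
    # pixel order: columns vary fastest within a row
    data[, , i] <- matrix(slope[1] * v + inter[1], nrow = cols)
  }
  ipp <- dcm_nums(s1[["00200032"]]); if (is.null(ipp)) ipp <- c(0, 0, zs[1])
  # DICOM world is LPS; our origin is RAS
  origin <- c(-ipp[1], -ipp[2], ipp[3])
  ct_volume(data,
            spacing = c(ps[2], ps[1], mean(dz)),
            origin = origin,
            axcodes = c("L", "P", "S"))
}
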