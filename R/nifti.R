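# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only what the pipeline needs: 3D/4D volumes, common scalar datatypes,
# voxel spacing from pixdim, scl_slope/scl_inter applied on read. Orientation
# handling is deliberately absent: masks and dynamic series produced and
# consumed by this package live on the same grid.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

.nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii`, optionally gzipped) into an
#' array with voxel spacing attached. 3D and 4D volumes are supported.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array), `spacing` (mm per
#'   axis, length 3) and `dim` (grid dimensions).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .nii_connection(path, "rb")
  on.exit(close(con), add = TRUE)

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "'")
  if (magic == "ni1") stop("two-file NIfTI (.hdr/.img) not supported")

  dim_field <- readBin(hdr_raw[41:56], "integer", n = 8L, size = 2L,
                       endian = endian)
  ndim <- dim_field[1]
  if (ndim < 3L || ndim > 4L) stop("expected a 3D or 4D volume, got ", ndim, "D")
  dims <- dim_field[2:(1 + ndim)]
  datatype <- readBin(hdr_raw[71:72], "integer", size = 2L, endian = endian)
  pixdim <- readBin(hdr_raw[77:108], "double", n = 8L, size = 4L,
                    endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", size = 4L, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", size = 4L, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", size = 4L, endian = endian)

  spec <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype)

  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n_vox <- prod(dims)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- array(vals, dim = dims)
  spacing <- pixdim[2:4]
  spacing[spacing <= 0 | !is.finite(spacing)] <- 1
  list(data = arr, spacing = spacing, dim = dims)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D or 4D array as a single-file NIfTI-1 image. Binary masks are
#' stored as uint8, everything else as float32.
#'
#' @param data Numeric/logical 3D or 4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm, length 3.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1)) {
  dims <- dim(data)
  if (is.null(dims) || !length(dims) %in% c(3L, 4L)) {
    stop("'data' must be a 3D or 4D array")
  }
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  is_mask <- is.logical(data) || all(data %in% c(0, 1))
  datatype <- if (is_mask) 2L else 16L
  bitpix <- if (is_mask) 8L else 32L

  hdr <- .build_nifti_header(dims, spacing, datatype, bitpix)
  con <- .nii_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  if (datatype == 2L) {
    writeBin(as.integer(data), con, size = 1L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 4L, endian = "little")
  }
  invisible(path)
}

.build_nifti_header <- function(dims, spacing, datatype, bitpix) {
  buf <- raw(352L)
  poke_i <- function(buf, off, x, size) {
    b <- writeBin(as.integer(x), raw(), size = size, endian = "little")
    buf[(off + 1):(off + length(b))] <- b
    buf
  }
  poke_f <- function(buf, off, x) {
    b <- writeBin(as.double(x), raw(), size = 4L, endian = "little")
    buf[(off + 1):(off + length(b))] <- b
    buf
  }
  buf <- poke_i(buf, 0L, 348L, 4L)
  dim_field <- c(length(dims), dims, rep(1L, 7L - length(dims)))
  buf <- poke_i(buf, 40L, dim_field, 2L)
  buf <- poke_i(buf, 70L, datatype, 2L)
  buf <- poke_i(buf, 72L, bitpix, 2L)
  buf <- poke_f(buf, 76L, c(1, spacing, rep(1, 4)))
  buf <- poke_f(buf, 108L, 352)
  buf <- poke_f(buf, 112L, c(1, 0))            # scl_slope, scl_inter
  buf <- poke_i(buf, 252L, 0L, 2L)             # qform_code
  buf <- poke_i(buf, 254L, 1L, 2L)             # sform_code
  buf <- poke_f(buf, 280L, c(spacing[1], 0, 0, 0))
  buf <- poke_f(buf, 296L, c(0, spacing[2], 0, 0))
  buf <- poke_f(buf, 312L, c(0, 0, spacing[3], 0))
  magic <- c(charToRaw("n+1"), as.raw(0L))
  buf[345:348] <- magic
  buf
}
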