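# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Supports 3D volumes with datatypes uint8, int16, int32, uint16, float32,
# float64, either endianness, and scl_slope/scl_inter rescaling. This is
# deliberately small: enough to round-trip the volumes this package itself
# produces and the co-registered, skull-stripped inputs it expects.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzipped) into a
#' [volume_grid()]. Only 3D images are accepted; `scl_slope`/`scl_inter`
#' are applied when set.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [volume_grid()] with the image values and the voxel spacing
#'   (mm) taken from `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read NIfTI file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("I/O error: truncated NIfTI header: ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("I/O error: not a NIfTI-1 file: ", path)
  }
  int16 <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1L):(off + 2L * n)], "integer", n = n, size = 2L, endian = endian)
  flt32 <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1L):(off + 4L * n)], "double", n = n, size = 4L, endian = endian)

  dims <- int16(40L, 8L)
  ndim <- dims[1L]
  if (!(ndim %in% c(3L, 4L)) || (ndim == 4L && dims[5L] > 1L))
    stop("I/O error: only 3D NIfTI volumes are supported (", path, ")")
  shape <- dims[2:4]
  datatype <- int16(70L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("I/O error: unsupported NIfTI datatype ", datatype)
  pixdim <- flt32(76L, 8L)
  vox_offset <- flt32(108L)
  scl_slope <- flt32(112L)
  scl_inter <- flt32(116L)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("I/O error: bad NIfTI magic in ", path)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("I/O error: truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume_grid(array(as.double(vals), dim = shape), spacing = pixdim[2:4])
}

#' Write a NIfTI-1 volume
#'
#' Writes a [volume_grid()] (or bare 3D array) as a single-file NIfTI-1
#' image, gzipped when the path ends in `.gz`. Integer-valued volumes
#' (label masks) are stored as int16, everything else as float32.
#'
#' @param grid A [volume_grid()] or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Spacing override when `grid` is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path, spacing = c(1, 1, 1)) {
  if (is.array(grid)) grid <- volume_grid(grid + 0, spacing = spacing)
  vals <- grid$values
  shape <- dim(vals)
  is_int <- all(vals == round(vals)) && max(abs(vals)) < 32767
  datatype <- if (is_int) 4L else 16L
  bitpix <- if (is_int) 16L else 32L

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_chr <- function(x, n) {
    r <- raw(n)
    b <- charToRaw(x)
    if (length(b)) r[seq_along(b)] <- b
    writeBin(r, con)
  }
  w_i32(348L)                         # sizeof_hdr
  w_chr("", 10L); w_chr("", 18L)      # data_type, db_name
  w_i32(0L); w_i16(0L); w_chr("r", 1L); w_chr("", 1L)  # extents..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L)) # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)        # intent_p*, intent_code
  w_i16(datatype); w_i16(bitpix); w_i16(0L)
  w_f32(c(1, grid$spacing, 1, 1, 1, 1))  # pixdim[8]
  w_f32(352)                          # vox_offset
  w_f32(1); w_f32(0)                  # scl_slope, scl_inter
  w_i16(0L); w_chr("", 1L)
  writeBin(as.raw(2L), con)           # xyzt_units: mm
  w_f32(c(0, 0, 0, 0))                # cal_max..toffset
  w_i32(c(0L, 0L))                    # glmax, glmin
  w_chr("radsubtype", 80L); w_chr("", 24L)
  w_i16(0L); w_i16(1L)                # qform_code, sform_code
  w_f32(rep(0, 6))                    # quatern, qoffset
  w_f32(c(grid$spacing[1], 0, 0, 0))  # srow_x
  w_f32(c(0, grid$spacing[2], 0, 0))  # srow_y
  w_f32(c(0, 0, grid$spacing[3], 0))  # srow_z
  w_chr("", 16L)
  w_chr("n+1", 4L)                    # magic
  writeBin(raw(4L), con)              # no extensions
  if (is_int) {
    w_i16(as.vector(vals))
  } else {
    w_f32(as.vector(vals))
  }
  invisible(path)
}
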