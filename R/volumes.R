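#' Brain volume container
#'
#' A light container for 3D label/coefficient volumes and 4D BOLD series:
#' a numeric array plus the two pieces of metadata the pipeline needs,
#' voxel size (mm) and repetition time (s). World coordinates are
#' `voxel_size_mm * 0-based voxel index` (axis-aligned grid, zero origin),
#' which is the convention all peak tables in this package report.
#'
#' @param data numeric array, 3 or 4 dimensions.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param tr_s repetition time in seconds (4D series) or `NA` (3D maps).
#' @return object of class `brain_volume`.
#' @export
brain_volume <- function(data, voxel_size_mm = c(3, 3, 3), tr_s = NA_real_) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != 3L && nd != 4L)
    stop("brain_volume: data must be a 3D or 4D array, got ", nd, "D")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("brain_volume: voxel_size_mm must be 3 positive numbers")
  structure(
    list(data = data, voxel_size_mm = as.numeric(voxel_size_mm),
         tr_s = as.numeric(tr_s)),
    class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("<brain_volume> ", paste(d, collapse = " x "),
      " | voxel ", paste(x$voxel_size_mm, collapse = "x"), " mm",
      if (!is.na(x$tr_s)) paste0(" | TR ", x$tr_s, " s"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.brain_volume <- function(x) dim(x$data)

#' Number of frames of a 4D volume
#' @param v a `brain_volume`.
#' @return integer frame count (1 for a 3D map).
#' @export
n_frames <- function(v) {
  d <- dim(v$data)
  if (length(d) == 4L) d[4L] else 1L
}

# NIfTI-1 constants; only the datatypes this pipeline reads/writes.
.nifti_dt <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE))  # uint16

#' Read a NIfTI-1 volume
#'
#' Minimal single-file (`.nii`) NIfTI-1 reader covering the datatypes
#' this pipeline writes or is likely to receive (uint8/16, int16/32,
#' float32/64), both endiannesses, and `scl_slope`/`scl_inter` scaling.
#' No R NIfTI package ships with the target environment, hence this
#' self-contained implementation; it is validated against nibabel in the
#' test suite.
#'
#' @param path path to an uncompressed `.nii` file.
#' @param require_4d error unless the image has 4 dimensions.
#' @return a [brain_volume].
#' @export
read_volume <- function(path, require_4d = FALSE) {
  if (!file.exists(path)) stop("read_volume: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (!identical(hdr_size, 348L)) {
    endian <- "big"
    seek(con, 0L)
    hdr_size <- readBin(con, "integer", 1L, size = 4L, endian = endian)
    if (!identical(hdr_size, 348L))
      stop("read_volume: not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  seek(con, 40L)
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  seek(con, 70L)
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  seek(con, 76L)
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  seek(con, 344L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("read_volume: unsupported magic (need single-file 'n+1'): ", path)

  nd <- dims[1L]
  if (nd < 3L || nd > 4L)
    stop("read_volume: only 3D/4D images supported, header says ", nd, "D")
  shape <- dims[2:(1L + nd)]
  if (any(shape < 1L)) stop("read_volume: inconsistent header dim: ",
                            paste(dims, collapse = ","))
  dt <- .nifti_dt[[as.character(datatype)]]
  if (is.null(dt)) stop("read_volume: unsupported NIfTI datatype code ",
                        datatype)
  n <- prod(shape)
  seek(con, as.integer(round(vox_offset)))
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n)
    stop("read_volume: truncated data section (expected ", n, " values)")
  if (is.finite(scl_slope) && scl_slope != 0 && scl_slope != 1)
    vals <- vals * scl_slope
  if (is.finite(scl_inter) && scl_inter != 0) vals <- vals + scl_inter
  v <- brain_volume(array(as.numeric(vals), dim = shape),
                    voxel_size_mm = pixdim[2:4],
                    tr_s = if (nd == 4L) pixdim[5L] else NA_real_)
  if (require_4d && length(dim(v$data)) != 4L)
    stop("read_volume: 4D image required but '", path, "' is ",
         length(dim(v$data)), "D")
  v
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file little-endian `.nii`. Doubles are stored as
#' float64 so a write/read round trip is bit-exact; the sform encodes
#' the axis-aligned voxel grid and `pixdim[4]` the TR.
#'
#' @param v a [brain_volume].
#' @param path output path (`.nii`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "brain_volume"))
  d <- dim(v$data)
  nd <- length(d)
  con <- file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                  # sizeof_hdr
  w_raw(36L)                                   # data_type..dim_info (unused)
  w_i16(c(nd, d, rep(1L, 7L - nd)))            # dim[8]
  w_f32(c(0, 0, 0))                            # intent_p1..p3
  w_i16(0L)                                    # intent_code
  w_i16(64L)                                   # datatype = FLOAT64
  w_i16(64L)                                   # bitpix
  w_i16(0L)                                    # slice_start
  tr <- if (!is.na(v$tr_s)) v$tr_s else 0
  w_f32(c(1, v$voxel_size_mm, tr, 0, 0, 0))    # pixdim[8] (qfac = 1)
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_i16(0L); w_raw(1L)                         # slice_end, slice_code
  writeBin(as.raw(10L), con)                   # xyzt_units: mm | sec
  w_f32(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i32(c(0L, 0L))                             # glmax, glmin
  w_raw(80L + 24L)                             # descrip, aux_file
  w_i16(0L); w_i16(1L)                         # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                             # quaternion + qoffset
  w_f32(c(v$voxel_size_mm[1], 0, 0, 0))        # srow_x
  w_f32(c(0, v$voxel_size_mm[2], 0, 0))        # srow_y
  w_f32(c(0, 0, v$voxel_size_mm[3], 0))        # srow_z
  w_raw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  w_raw(4L)                                    # extension indicator
  writeBin(as.numeric(v$data), con, size = 8L, endian = "little")
  invisible(path)
}
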