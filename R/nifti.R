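# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# The offline R stack ships no neuroimaging I/O package, so the 348-byte
# NIfTI-1 header is handled directly. Scope: 3-D volumes, little- or
# big-endian input, datatypes uint8 / int16 / int32 / float32 / float64,
# scl_slope/scl_inter honoured on read; output is always little-endian
# float32 with the affine stored in the sform (sform_code = 1).

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric 3-D array), `affine` (4x4 voxel-to-world
#'   matrix, RAS), `voxel_size_mm` (length-3 positive numeric).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("NIfTI file not found: %s", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stopf("truncated NIfTI header in %s", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stopf("not a NIfTI-1 file (bad sizeof_hdr): %s", path)
  }
  rd <- function(off, what, size, n = 1L, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian, signed = signed)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("bad NIfTI magic '%s' in %s", magic, path)
  dim       <- rd(40L, "integer", 2L, n = 8L)
  datatype  <- rd(70L, "integer", 2L)
  pixdim    <- rd(76L, "double", 4L, n = 8L)
  vox_offset <- rd(108L, "double", 4L)
  scl_slope <- rd(112L, "double", 4L)
  scl_inter <- rd(116L, "double", 4L)
  sform_code <- rd(254L, "integer", 2L)
  srow <- rbind(rd(280L, "double", 4L, n = 4L),
                rd(296L, "double", 4L, n = 4L),
                rd(312L, "double", 4L, n = 4L))
  ndim <- dim[1]
  if (ndim < 3L || any(dim[2:4] < 1L)) stopf("expected a 3-D volume in %s", path)
  if (ndim > 3L && any(dim[5:(1 + ndim)] > 1L))
    stopf("4-D series are out of scope: %s", path)
  shape <- dim[2:4]
  spec <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(spec)) stopf("unsupported NIfTI datatype %d in %s", datatype, path)
  # skip to vox_offset (gz connections cannot seek reliably)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n_vox <- prod(shape)
  vals <- readBin(con, spec$what, n = n_vox, size = spec$size,
                  endian = endian, signed = spec$signed)
  if (length(vals) < n_vox) stopf("truncated voxel data in %s", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  data <- array(vals, dim = shape)
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  voxel_size_mm <- abs(pixdim[2:4])
  list(data = data, affine = affine, voxel_size_mm = voxel_size_mm)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param data numeric 3-D array.
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param affine 4x4 voxel-to-world matrix (RAS); default scaled identity.
#' @param voxel_size_mm voxel edge lengths in mm (length 1 or 3).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = NULL, voxel_size_mm = 3) {
  if (length(dim(data)) != 3L) stopf("write_nifti expects a 3-D array")
  if (!all(is.finite(data))) stopf("non-finite voxels cannot be written")
  vs <- rep_len(as.double(voxel_size_mm), 3L)
  if (any(vs <= 0)) stopf("voxel sizes must be positive")
  if (is.null(affine)) affine <- diag(c(vs, 1))
  if (!identical(dim(affine), c(4L, 4L))) stopf("affine must be 4x4")
  shape <- dim(data)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                             # sizeof_hdr
  w_raw(36L)                              # data_type..dim_info
  w_i16(c(3L, shape, 1L, 1L, 1L, 1L))     # dim[8]
  w_f32(c(0, 0, 0))                       # intent_p1..p3
  w_i16(0L)                               # intent_code
  w_i16(16L); w_i16(32L); w_i16(0L)       # datatype float32, bitpix, slice_start
  w_f32(c(1, vs, 1, 1, 1, 1))             # pixdim[8] (qfac = 1)
  w_f32(352)                              # vox_offset
  w_f32(1); w_f32(0)                      # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                    # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                    # cal_max..toffset
  w_i32(c(0L, 0L))                        # glmax, glmin
  w_raw(104L)                             # descrip + aux_file
  w_i16(0L); w_i16(1L)                    # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))              # quatern + qoffset
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_raw(16L)                              # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  w_raw(4L)                               # extension flag
  writeBin(as.double(data), con, size = 4L, endian = "little")
  invisible(path)
}
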