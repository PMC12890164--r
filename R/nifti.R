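# Minimal NIfTI-1 I/O.
#
# The installed R stack has no NIfTI package, so the subset of NIfTI-1 this
# tool needs is implemented directly: single-file .nii / .nii.gz, 3D scalar
# volumes and 4D multi-channel fields, float32/float64/int8..int32 storage,
# voxel spacing via pixdim, scl_slope/scl_inter honoured on read. The affine
# is written as a diagonal sform (RAS, spacing on the diagonal): array order
# (i,j,k) maps directly to the first three NIfTI dimensions.

.NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as a NIfTI-1 file
#'
#' @param a numeric 3D array (volume, mask) or 4D array (multi-channel CAM).
#' @param path output path; `.nii` or `.nii.gz`.
#' @param spacing voxel spacing in mm (3 values).
#' @param datatype `"float32"` (default) or `"int16"` (label maps).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(a, path, spacing = c(1, 1, 1),
                        datatype = c("float32", "int16")) {
  datatype <- match.arg(datatype)
  nd <- length(dim(a))
  assert_that(nd %in% c(3L, 4L), "write_nifti: array must be 3D or 4D")
  dm <- dim(a)
  code <- if (datatype == "float32") 16L else 4L
  bitpix <- if (datatype == "float32") 32L else 16L
  con <- .nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # unused legacy fields
  dimv <- integer(8)
  dimv[1] <- nd
  dimv[seq_len(nd) + 1] <- dm
  dimv[(nd + 2):8][dimv[(nd + 2):8] == 0] <- 1L
  writeBin(as.integer(dimv), con, size = 2)           # dim
  writeBin(raw(14), con)                              # intent_p1..intent_code
  writeBin(as.integer(c(code, bitpix, 0L)), con, size = 2)  # datatype,bitpix,slice_start
  pixdim <- c(1, spacing, 1, 1, 1, 1)
  writeBin(pixdim, con, size = 4)                     # pixdim[0..7]
  writeBin(c(352, 1, 0), con, size = 4)               # vox_offset, scl_slope, scl_inter
  writeBin(raw(2 + 1 + 1), con)                       # slice_end, slice_code, xyzt_units
  writeBin(raw(24), con)                              # cal_max..glmin
  writeBin(raw(80 + 24), con)                         # descrip, aux_file
  writeBin(as.integer(c(0L, 1L)), con, size = 2)      # qform_code=0, sform_code=1
  writeBin(numeric(6), con, size = 4)                 # quatern b,c,d + qoffset x,y,z... (first 6 floats)
  srow <- c(spacing[1], 0, 0, 0,  0, spacing[2], 0, 0,  0, 0, spacing[3], 0)
  writeBin(srow, con, size = 4)                       # srow_x, srow_y, srow_z
  writeBin(charToRaw(sprintf("%-16s", "cavitygraph")), con)  # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)       # magic
  writeBin(raw(4), con)                               # extension flag
  if (datatype == "float32") {
    writeBin(as.numeric(a), con, size = 4)
  } else {
    writeBin(as.integer(round(a)), con, size = 2)
  }
  invisible(path)
}

#' Read a NIfTI-1 file written by this package (or any single-file NIfTI-1)
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return array (3D or 4D) with attribute `spacing` (mm triple).
#' @export
read_nifti <- function(path) {
  con <- .nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  sizeof <- readBin(hdr[1:4], "integer", size = 4)
  endian <- "little"
  if (sizeof != 348L) {
    sizeof <- readBin(hdr[1:4], "integer", size = 4, endian = "big")
    assert_that(sizeof == 348L, "read_nifti: not a NIfTI-1 file")
    endian <- "big"
  }
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n = n, size = 4, endian = endian)
  dimv <- rd_i16(40, 8)
  nd <- dimv[1]
  assert_that(nd >= 3 && nd <= 4, "read_nifti: only 3D/4D images supported")
  dm <- dimv[2:(nd + 1)]
  datatype <- rd_i16(70, 1)
  spec <- .NIFTI_DTYPES[[as.character(datatype)]]
  assert_that(!is.null(spec), sprintf("read_nifti: unsupported datatype %d", datatype))
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  n <- prod(dm)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(as.numeric(vals), dm)
  attr(out, "spacing") <- pixdim[2:4]
  out
}
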