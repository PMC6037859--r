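# Minimal NIfTI-1 single-file (.nii / .nii.gz) input/output.
#
# Only what the synthetic pipeline needs: little-endian float32 (datatype 16)
# and uint8 (datatype 2) arrays of up to 4 dimensions, identity-like affine
# via pixdim, no extensions. Written against the NIfTI-1.1 header layout.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 volume
#'
#' @param data numeric (written as float32) or integer 0-255 array with
#'   `datatype = "uint8"`; up to 4 dimensions.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param pixdim voxel sizes per dimension (mm, mm, mm, s); recycled/padded.
#' @param datatype `"float32"` (default) or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1, 1),
                        datatype = c("float32", "uint8")) {
  datatype <- match.arg(datatype)
  dims <- dim(data)
  if (is.null(dims)) stop("data must be an array", call. = FALSE)
  if (length(dims) > 4) stop("at most 4 dimensions supported", call. = FALSE)
  dim8 <- c(length(dims), dims, rep(1L, 7 - length(dims)))
  pd8 <- c(0, pixdim, rep(1, 7 - length(pixdim)))[1:8]
  dtcode <- if (datatype == "float32") 16L else 2L
  bitpix <- if (datatype == "float32") 32L else 8L

  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                       # sizeof_hdr
  writeBin(raw(35), con)            # data_type[10], db_name[18], extents, ...
  writeBin(as.raw(0L), con)         # dim_info
  wi(dim8, 2)                       # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2)                         # intent_code
  wi(dtcode, 2); wi(bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(pd8)                           # pixdim[8]
  wf(352)                           # vox_offset
  wf(c(1, 0))                       # scl_slope, scl_inter
  wi(0L, 2); writeBin(raw(2), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  writeBin(raw(104), con)           # descrip[80] + aux_file[24]
  wi(c(0L, 0L), 2)                  # qform_code, sform_code (0 = arbitrary)
  wf(rep(0, 6))                     # quatern b,c,d, qoffset x,y,z
  wf(c(pd8[2], 0, 0, 0,  0, pd8[3], 0, 0,  0, 0, pd8[4], 0))  # srow (informative)
  writeBin(raw(16), con)            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)             # extension flag
  if (datatype == "float32") {
    writeBin(as.double(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(data), con, size = 1, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_nifti()]
#'
#' Supports little-endian float32/uint8 single-file NIfTI-1.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return array with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sizeof <- readBin(hdr[1:4], "integer", 1, 4, endian = "little")
  if (sizeof != 348)
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  dim8 <- readBin(hdr[41:56], "integer", 8, 2, endian = "little")
  dtcode <- readBin(hdr[71:72], "integer", 1, 2, endian = "little")
  pixdim <- readBin(hdr[77:108], "double", 8, 4, endian = "little")
  vox_offset <- readBin(hdr[109:112], "double", 1, 4, endian = "little")
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic: ", magic, call. = FALSE)
  dims <- dim8[seq_len(dim8[1]) + 1]
  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  data <- switch(as.character(dtcode),
    "16" = readBin(con, "double", n, 4, endian = "little"),
    "2" = as.numeric(readBin(con, "integer", n, 1, signed = FALSE,
                             endian = "little")),
    stop("unsupported NIfTI datatype code ", dtcode, call. = FALSE))
  structure(array(data, dims), pixdim = pixdim[seq_len(dim8[1]) + 1])
}
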