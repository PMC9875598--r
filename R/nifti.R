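#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes uncompressed single-file NIfTI-1 (`.nii`) volumes so
#' that externally produced masks and fields (e.g. atlas sweet spots) can
#' be exchanged with standard neuroimaging tools. Only the subset needed
#' here is supported: 3-D volumes, datatypes uint8/int16/int32/float32/
#' float64, an axis-aligned sform (RAS mm, voxel-centre convention), no
#' compression and no extensions. Scaling via `scl_slope`/`scl_inter` is
#' honoured on read.
#'
#' @param path File path ending in `.nii`.
#' @param values 3-D numeric array to write.
#' @param grid A `dbs_grid` giving origin and isotropic voxel size.
#' @param datatype `"float32"` (default) or `"uint8"` (for masks).
#' @return `read_nifti()` returns a list with `values` (3-D array) and
#'   `grid` (a `dbs_grid`); `write_nifti()` returns `path` invisibly.
#' @export
write_nifti <- function(values, grid, path, datatype = "float32") {
  stopifnot(length(dim(values)) == 3, inherits(grid, "dbs_grid"))
  dt <- switch(datatype,
    uint8 = list(code = 2L, bitpix = 8L),
    float32 = list(code = 16L, bitpix = 32L),
    stop("unsupported write datatype: ", datatype)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # unused through dim_info
  wi(c(3L, dim(values), 1L, 1L, 1L, 1L), 2)     # dim[8]
  wf(c(0, 0, 0))                                # intent_p1..p3
  wi(0L, 2)                                     # intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(c(1, rep(grid$voxel_mm, 3), 1, 1, 1, 1))   # pixdim[8] (qfac = 1)
  wf(352)                                       # vox_offset
  wf(c(1, 0))                                   # scl_slope, scl_inter
  wi(0L, 2)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)              # slice_code, xyzt_units = mm
  wf(c(0, 0, 0, 0))                             # cal_max/min, slice_duration, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code = 0, sform_code = 1
  wf(rep(0, 6))                                 # quaternions b,c,d + offsets x,y,z
  wf(c(grid$voxel_mm, 0, 0, grid$origin[1]))    # srow_x
  wf(c(0, grid$voxel_mm, 0, grid$origin[2]))    # srow_y
  wf(c(0, 0, grid$voxel_mm, grid$origin[3]))    # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(values)), con)
  } else {
    writeBin(as.double(values), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = size > 2 || size == 2)
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dims <- ri(40, 2, 8)
  if (any(dims[5:8] > 1)) stop("only 3-D NIfTI volumes are supported")
  d <- dims[2:4]
  datatype <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  sform_code <- ri(254, 2)
  srow <- matrix(rf(280, 12), nrow = 3, byrow = TRUE)
  n <- prod(d)
  seek(con, where = vox_offset, origin = "start")
  vals <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = "little")),
    "8" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code: ", datatype)
  )
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  voxel <- pixdim[2]
  if (sform_code > 0) {
    if (any(abs(srow[, 1:3] - diag(rep(voxel, 3))) > 1e-4 * max(voxel, 1)))
      stop("only axis-aligned RAS sforms are supported")
    origin <- srow[, 4]
  } else {
    origin <- c(0, 0, 0)
  }
  if (max(abs(pixdim[2:4] - voxel)) > 1e-6)
    stop("only isotropic voxels are supported")
  grid <- structure(list(origin = origin, voxel_mm = voxel, dim = d),
                    class = "dbs_grid")
  list(values = array(vals, dim = d), grid = grid)
}

#' Read a binary mask from NIfTI
#'
#' Values are binarised with `value > threshold`.
#' @param path NIfTI file path.
#' @param threshold Binarisation threshold (default 0.5).
#' @return A `dbs_mask`.
#' @export
read_mask_nifti <- function(path, threshold = 0.5) {
  v <- read_nifti(path)
  new_mask_image(array(as.numeric(v$values > threshold), dim = v$grid$dim),
                 v$grid)
}
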