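# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Implements the subset of the format the pipeline needs: little- or
# big-endian headers, datatypes uint8/int16/int32/float32/float64,
# scl_slope/scl_inter scaling, sform (preferred) or qform affines.
# Written here because no R NIfTI package is available in the target
# environment; nibabel serves as an independent oracle in the test suite.

NIFTI_DT <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE))   # float64

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 image
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`) and returns a
#' package object according to `as`: a 4D run (with TR taken from
#' `pixdim[4]`), a 3D scalar map, or a brain mask. NaN voxels are rejected
#' with an error, as downstream statistics assume complete grids.
#'
#' @param path File path.
#' @param as `"auto"` (4D file becomes `fmri_4d`, 3D becomes `scalar_map`),
#'   or one of `"fmri"`, `"map"`, `"mask"`.
#' @param kind Map kind forwarded to [scalar_map()] when a map is returned.
#' @param subject_id Subject id attached to a returned run.
#' @return An [fmri_4d()], [scalar_map()] or [brain_mask()].
#' @export
read_nifti <- function(path, as = c("auto", "fmri", "map", "mask"),
                       kind = "generic", subject_id = NULL) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path, call. = FALSE)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path, call. = FALSE)
  }
  rd <- function(off, what, n, size)
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n, size,
            endian = endian)
  dim0     <- rd(40L, "integer", 8L, 2L)
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim   <- rd(76L, "double", 8L, 4L)
  vox_off  <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  quatern    <- rd(256L, "double", 3L, 4L)
  qoffset    <- rd(268L, "double", 3L, 4L)
  srow       <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path, call. = FALSE)

  ndim <- dim0[1]
  if (ndim < 3L || ndim > 4L)
    stop(sprintf("unsupported image dimensionality %d in %s", ndim, path),
         call. = FALSE)
  dims <- dim0[2:(1 + ndim)]
  nvox <- prod(dims)

  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop("unsupported NIfTI datatype code ", datatype, call. = FALSE)

  seek(con, where = vox_off, origin = "start")
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox)
    stop("truncated NIfTI data section: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("NIfTI image contains NaN/Inf voxels: ", path, call. = FALSE)
  arr <- array(as.double(vals), dim = dims)

  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else if (qform_code > 0L) {
    affine <- qform_to_affine(quatern, qoffset, pixdim)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }

  if (as == "auto") as <- if (ndim == 4L) "fmri" else "map"
  switch(as,
    fmri = {
      if (ndim != 4L) stop("expected a 4D image, got 3D: ", path, call. = FALSE)
      tr <- pixdim[5]
      if (!is.finite(tr) || tr <= 0)
        stop("4D image has no usable TR in pixdim[4]: ", path, call. = FALSE)
      fmri_4d(arr, tr_s = tr, affine = affine,
              subject_id = subject_id %||% sub("\\.nii(\\.gz)?$", "", basename(path)))
    },
    map = {
      if (ndim != 3L) stop("expected a 3D image, got 4D: ", path, call. = FALSE)
      scalar_map(arr, affine = affine, kind = kind)
    },
    mask = {
      if (ndim != 3L) stop("expected a 3D mask, got 4D: ", path, call. = FALSE)
      brain_mask(arr != 0, affine = affine)
    })
}

# NIfTI-1 quaternion (method 2) voxel-to-world transform
qform_to_affine <- function(quatern, qoffset, pixdim) {
  b <- quatern[1]; c <- quatern[2]; d <- quatern[3]
  a2 <- 1 - b^2 - c^2 - d^2
  a <- if (a2 < 1e-7) 0 else sqrt(a2)
  R <- matrix(c(
    a*a + b*b - c*c - d*d, 2*b*c - 2*a*d,         2*b*d + 2*a*c,
    2*b*c + 2*a*d,         a*a + c*c - b*b - d*d, 2*c*d - 2*a*b,
    2*b*d - 2*a*c,         2*c*d + 2*a*b,         a*a + d*d - b*b - c*c),
    nrow = 3L, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  sp <- c(pixdim[2], pixdim[3], qfac * pixdim[4])
  affine <- diag(4)
  affine[1:3, 1:3] <- R %*% diag(sp)
  affine[1:3, 4] <- qoffset
  affine
}

#' Write a NIfTI-1 image
#'
#' Writes an [fmri_4d()], [scalar_map()], [brain_mask()] or bare numeric
#' array as a single-file little-endian NIfTI-1 image (float32 by default;
#' masks as uint8). `.gz` paths are gzip-compressed. The affine is stored in
#' the sform (code 2); TR goes to `pixdim[4]` for 4D images.
#'
#' @param x Image object or array.
#' @param path Destination path ending in `.nii` or `.nii.gz`.
#' @param affine,tr_s Used when `x` is a bare array.
#' @param datatype `"float32"` or `"float64"` (`"uint8"` chosen for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, affine = NULL, tr_s = NULL,
                        datatype = "float32") {
  if (inherits(x, "fmri_4d")) {
    arr <- x$data; affine <- x$affine; tr_s <- x$tr_s
  } else if (inherits(x, "scalar_map")) {
    arr <- x$data; affine <- x$affine
  } else if (inherits(x, "brain_mask")) {
    arr <- x$data + 0; affine <- x$affine; datatype <- "uint8"
  } else if (is.array(x)) {
    arr <- x
    if (is.null(affine)) affine <- diag(4)
  } else stop("cannot write object of class ", class(x)[1], call. = FALSE)
  dims <- dim(arr)
  ndim <- length(dims)
  if (!ndim %in% c(3L, 4L)) stop("only 3D/4D images supported", call. = FALSE)
  if (ndim == 4L && is.null(tr_s)) tr_s <- 1

  dtcode <- switch(datatype, uint8 = 2L, float32 = 16L, float64 = 64L,
                   stop("unsupported write datatype ", datatype, call. = FALSE))
  bitpix <- switch(datatype, uint8 = 8L, float32 = 32L, float64 = 64L)
  vsz <- voxel_sizes(affine)

  con <- nifti_open(path, "wb")
  on.exit(close(con))
  w_i4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f4 <- function(v) writeBin(as.double(v), con, size = 4L, endian = "little")
  w_ch <- function(s, n) {
    r <- charToRaw(s)
    writeBin(c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r)))), con)
  }
  w_i4(348L)                       # sizeof_hdr
  w_ch("", 10L); w_ch("", 18L)     # data_type, db_name (unused)
  w_i4(0L); w_i2(0L)               # extents, session_error
  writeBin(as.raw(c(114L, 0L)), con)  # regular = 'r', dim_info
  dimv <- rep(1L, 8L); dimv[1] <- ndim; dimv[2:(1 + ndim)] <- dims
  w_i2(dimv)
  w_f4(c(0, 0, 0)); w_i2(0L)       # intent_p1-3, intent_code
  w_i2(dtcode); w_i2(bitpix); w_i2(0L)  # datatype, bitpix, slice_start
  pixdim <- rep(0, 8); pixdim[1] <- 1; pixdim[2:4] <- vsz
  if (ndim == 4L) pixdim[5] <- tr_s
  w_f4(pixdim)
  w_f4(352)                        # vox_offset
  w_f4(1); w_f4(0)                 # scl_slope, scl_inter
  w_i2(0L); writeBin(as.raw(c(0L, 10L)), con)  # slice_end, slice_code, xyzt_units (mm|sec)
  w_f4(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))                  # glmax, glmin
  w_ch("alffkit", 80L); w_ch("", 24L)  # descrip, aux_file
  w_i2(0L); w_i2(2L)               # qform_code, sform_code (aligned)
  w_f4(c(0, 0, 0)); w_f4(c(0, 0, 0))   # quatern, qoffset
  w_f4(t(affine[1:3, , drop = FALSE])) # srow_x, srow_y, srow_z
  w_ch("", 16L)
  w_ch("n+1", 4L)
  writeBin(raw(4L), con)           # extension flag: none
  if (datatype == "uint8") {
    writeBin(as.integer(arr), con, size = 1L)
  } else {
    writeBin(as.double(arr), con, size = bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
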