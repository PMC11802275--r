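# Minimal NIfTI-1 I/O.
#
# None of the installed R stacks here ship a NIfTI reader, so the package
# carries its own single-file implementation of the parts of NIfTI-1 a QSM
# pipeline needs: 3D volumes, the common scalar datatypes, scl_slope/inter
# scaling, pixdim voxel geometry, a diagonal sform, and transparent gzip
# (.nii or .nii.gz).  It is deliberately not a general NIfTI library: no
# 4D+ data, no extensions, no qform quaternions beyond identity.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE,  bitpix = 64L),
  `512` = list(what = "integer", size = 2L, signed = FALSE, bitpix = 16L)
)

#' Read a 3D NIfTI-1 volume
#'
#' Parses the 348-byte NIfTI-1 header (either byte order), applies
#' `scl_slope`/`scl_inter` scaling, and returns the voxel array together
#' with its geometry.  Only 3D single-frame volumes are accepted; 4D input
#' is rejected with a dimension report, since every stage of this pipeline
#' is defined on a single echo.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with elements `data` (3D numeric array), `voxel_size_mm`
#'   (length-3 numeric), `affine` (4x4 matrix from the sform rows, or a
#'   diagonal pixdim affine when no sform is set), `datatype` (NIfTI code).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- .Platform$endian
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- if (endian == "little") "big" else "little"
    if (.swap_int32(sizeof_hdr) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36L)                                    # unused fields
  dim8 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                                    # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)     # bitpix
  readBin(con, "raw", 2L)                                     # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)                                   # through aux_file
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "numeric", 6L, size = 4L, endian = endian)     # quaternion
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                                    # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop("unrecognized NIfTI magic '", magic, "' in ", path)

  ndim <- dim8[1L]
  if (ndim > 3L && any(dim8[seq(5L, 1L + ndim)] > 1L))
    stop("only 3D volumes are supported; file is ", ndim, "D with dim ",
         paste(dim8[2:(1L + ndim)], collapse = " x "), ": ", path)
  d <- pmax(dim8[2:4], 1L)

  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  # Header reads above consume exactly 348 bytes; skip forward to the data
  # (gz connections only support forward reads, so no seek()).
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(d)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && (is.na(scl_inter) || scl_inter == 0)))
    vals <- vals * scl_slope + ifelse(is.na(scl_inter), 0, scl_inter)
  arr <- array(as.numeric(vals), dim = d)
  voxel <- pixdim[2:4]
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1:3, ] <- srow
  } else {
    diag(affine)[1:3] <- voxel
  }
  list(data = arr, voxel_size_mm = voxel, affine = affine, datatype = datatype)
}

.swap_int32 <- function(x) {
  b <- writeBin(as.integer(x), raw(), size = 4L)
  readBin(rev(b), "integer", 1L, size = 4L)
}

#' Write a 3D array as NIfTI-1
#'
#' Writes float32 (default) or float64 data with the voxel size recorded in
#' `pixdim` and a diagonal sform.  Gzip compression is chosen from the file
#' extension.
#'
#' @param x 3D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param datatype `"float32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_size_mm = c(1, 1, 1),
                        datatype = c("float32", "float64")) {
  stopifnot(length(dim(x)) == 3L, length(voxel_size_mm) == 3L)
  datatype <- match.arg(datatype)
  code <- if (datatype == "float32") 16L else 64L
  size <- if (datatype == "float32") 4L else 8L
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, s) writeBin(as.integer(v), con, size = s, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L, 4L)
  writeBin(raw(36L), con)
  wi(c(3L, dim(x), 1L, 1L, 1L, 1L), 2L)                 # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2L)                            # intent
  wi(code, 2L); wi(8L * size, 2L); wi(0L, 2L)           # datatype, bitpix
  wf(c(1, voxel_size_mm, 1, 1, 1, 1))                   # pixdim[8]
  wf(352); wf(1); wf(0)                                 # vox_offset, scl
  wi(0L, 2L); writeBin(raw(1L), con); writeBin(as.raw(2L), con)  # xyzt: mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4L)                  # cal/glmax
  writeBin(raw(80L + 24L), con)                         # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)                                # qform, sform codes
  wf(c(0, 0, 0, 0, 0, 0))                               # quaternion
  wf(c(voxel_size_mm[1L], 0, 0, 0))                     # srow_x
  wf(c(0, voxel_size_mm[2L], 0, 0))                     # srow_y
  wf(c(0, 0, voxel_size_mm[3L], 0))                     # srow_z
  writeBin(raw(16L), con)                               # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)           # magic
  writeBin(raw(4L), con)                                # extension flag
  writeBin(as.numeric(x), con, size = size, endian = "little")
  invisible(path)
}

#' Check two volumes share a grid
#'
#' Affine/grid agreement guard used before combining volumes (e.g. an OEF
#' map with a label atlas).
#'
#' @param a,b results of [read_nifti()] or lists with `data` and
#'   `voxel_size_mm`.
#' @param tol tolerance on voxel size / affine entries.
#' @return invisibly `TRUE`; stops with a diagnostic on mismatch.
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  if (!identical(dim(a$data), dim(b$data)))
    stop("grid mismatch: dimensions ", paste(dim(a$data), collapse = "x"),
         " vs ", paste(dim(b$data), collapse = "x"))
  if (max(abs(a$voxel_size_mm - b$voxel_size_mm)) > tol)
    stop("grid mismatch: voxel sizes differ")
  if (!is.null(a$affine) && !is.null(b$affine) &&
      max(abs(a$affine - b$affine)) > tol)
    stop("grid mismatch: affines differ")
  invisible(TRUE)
}
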