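# V-SHARP background-field removal.  A spherical mean value (SMV) filter
# annihilates harmonic fields (the mean-value property), so applying
# (I - SMV) removes background fields generated by sources outside the
# brain while leaving local dipole fields largely intact.  V-SHARP applies
# (I - SMV) with the largest sphere that fits inside the mask at each
# voxel -- big spheres deep inside, small ones near the boundary -- and
# then deconvolves by the largest-kernel operator with TSVD truncation.

#' V-SHARP parameters
#'
#' @param radii_voxels strictly decreasing sphere radii in units of the
#'   smallest voxel edge (default `c(25, 20, 15, 10, 5, 3, 2, 1)`).
#'   Converted internally to millimetres via the smallest voxel edge, so
#'   spheres respect physical distance on anisotropic grids.
#' @param tsvd_threshold spectral magnitude below which the deconvolution
#'   is truncated; in `(0, 1)`, default 0.05.
#' @return object of class `vsharp_params`.
#' @export
vsharp_params <- function(radii_voxels = c(25, 20, 15, 10, 5, 3, 2, 1),
                          tsvd_threshold = 0.05) {
  stopifnot(length(radii_voxels) >= 1, all(radii_voxels >= 1),
            all(diff(radii_voxels) < 0),
            tsvd_threshold > 0, tsvd_threshold < 1)
  structure(list(radii_voxels = radii_voxels,
                 tsvd_threshold = tsvd_threshold),
            class = "vsharp_params")
}

# Normalized spherical kernel (sums to 1), origin-centred with wrap-around,
# rasterized in millimetre space so anisotropic voxels give physically
# spherical kernels.
.smv_kernel <- function(dim, voxel_size_mm, radius_mm) {
  dist_axis <- function(n, v) pmin(seq_len(n) - 1L, n - (seq_len(n) - 1L)) * v
  dx <- array(dist_axis(dim[1L], voxel_size_mm[1L]), dim = dim)
  dy <- array(rep(dist_axis(dim[2L], voxel_size_mm[2L]), each = dim[1L]),
              dim = dim)
  dz <- array(rep(dist_axis(dim[3L], voxel_size_mm[3L]),
                  each = dim[1L] * dim[2L]), dim = dim)
  k <- (dx^2 + dy^2 + dz^2) <= radius_mm^2
  array(as.numeric(k) / sum(k), dim = dim)
}

#' Spherical mean value filter
#'
#' Replaces each voxel by the mean of the field over a sphere of the given
#' radius (spectral convolution with a normalized spherical kernel).
#'
#' @param field 3D field array.
#' @param radius_mm sphere radius in millimetres.
#' @param voxel_size_mm voxel size (mm).
#' @return filtered field of the same shape.
#' @export
smv_filter <- function(field, radius_mm, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(radius_mm >= min(voxel_size_mm))
  if (radius_mm > min(dim(field) * voxel_size_mm) / 2)
    stop("SMV radius ", radius_mm, " mm exceeds half the smallest volume",
         " extent (", min(dim(field) * voxel_size_mm), " mm)")
  k <- .smv_kernel(dim(field), voxel_size_mm, radius_mm)
  ifft3_real(fft3(field) * fft3(k))
}

#' V-SHARP background field removal
#'
#' For each voxel, applies `(I - SMV_r)` with the largest radius `r` in
#' the schedule whose sphere fits entirely inside the mask at that voxel;
#' voxels where not even the smallest sphere fits are excluded (the eroded
#' mask).  The combined high-pass field is then deconvolved by the
#' largest-kernel operator `(1 - SMV_rmax)` in the spectral domain, with
#' spectral values of magnitude below `tsvd_threshold` truncated to zero.
#'
#' @param total_field 3D field array (ppm), valid inside `mask`.
#' @param mask logical brain mask.
#' @param params [vsharp_params()].
#' @param voxel_size_mm voxel size (mm).
#' @return list with `tissue_field` (ppm, zero outside the eroded mask)
#'   and `eroded_mask` (logical).
#' @export
vsharp <- function(total_field, mask, params = vsharp_params(),
                   voxel_size_mm = c(1, 1, 1)) {
  dim3 <- dim(total_field)
  radii_mm <- params$radii_voxels * min(voxel_size_mm)
  if (max(radii_mm) > min(dim3 * voxel_size_mm) / 2)
    stop("largest V-SHARP radius (", max(radii_mm), " mm) exceeds half the",
         " smallest volume extent; shrink the schedule")
  fhat <- fft3(total_field)
  maskc <- fft3(array(as.numeric(!mask), dim = dim3))
  combined <- array(0, dim = dim3)
  assigned <- array(FALSE, dim = dim3)
  khat_max <- NULL
  eroded <- NULL
  for (r in radii_mm) {
    k <- .smv_kernel(dim3, voxel_size_mm, r)
    khat <- fft3(k)
    if (is.null(khat_max)) khat_max <- khat
    # sphere fits <=> no outside-mask voxel within the kernel support
    fits <- mask & (ifft3_real(maskc * khat) < 0.5 / sum(k > 0))
    eroded <- fits    # schedule is decreasing: last (smallest) radius wins
    hp <- total_field - ifft3_real(fhat * khat)
    sel <- fits & !assigned
    combined[sel] <- hp[sel]
    assigned <- assigned | fits
  }
  if (!any(assigned))
    stop("mask too thin: no voxel admits even the smallest SMV sphere (",
         min(radii_mm), " mm)")
  chat <- 1 - khat_max
  inv <- ifelse(Mod(chat) >= params$tsvd_threshold, 1 / chat, 0)
  tissue <- ifft3_real(fft3(combined) * inv)
  tissue[!eroded] <- 0
  list(tissue_field = tissue, eroded_mask = eroded)
}
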