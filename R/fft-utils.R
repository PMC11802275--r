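# Spectral helpers shared by the forward model, unwrapping, V-SHARP and
# the dipole inversions.  All operators assume periodic boundaries; callers
# that need isolation (the unwrapper) zero-pad first.

#' Discrete Fourier frequencies
#'
#' Frequencies in cycles per sample for an `n`-point DFT, in the native
#' (unshifted) FFT ordering: `0, 1/n, ..., -2/n, -1/n`.
#'
#' @param n number of samples.
#' @return numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n) {
  (((seq_len(n) - 1L) + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' 3D spatial-frequency grids
#'
#' Builds the three k-coordinate arrays (cycles per mm) for a volume with
#' the given dimensions and voxel size.
#'
#' @param dim integer 3-vector of array dimensions.
#' @param voxel_size_mm numeric 3-vector of voxel edge lengths (mm).
#' @return list with arrays `kx`, `ky`, `kz` and `k2 = kx^2 + ky^2 + kz^2`.
#' @keywords internal
k_grid <- function(dim, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim) == 3L, length(voxel_size_mm) == 3L,
            all(voxel_size_mm > 0))
  fx <- fft_freq(dim[1L]) / voxel_size_mm[1L]
  fy <- fft_freq(dim[2L]) / voxel_size_mm[2L]
  fz <- fft_freq(dim[3L]) / voxel_size_mm[3L]
  kx <- array(fx, dim = dim)
  ky <- array(rep(fy, each = dim[1L]), dim = dim)
  kz <- array(rep(fz, each = dim[1L] * dim[2L]), dim = dim)
  list(kx = kx, ky = ky, kz = kz, k2 = kx^2 + ky^2 + kz^2)
}

#' Forward and inverse 3D FFT
#' @param x numeric or complex array.
#' @return complex array (`fft3`) / real array (`ifft3_real`, the real part
#'   of the normalized inverse transform).
#' @keywords internal
fft3 <- function(x) stats::fft(x)

#' @rdname fft3
#' @keywords internal
ifft3_real <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

#' Unit dipole kernel in k-space
#'
#' The Lorentz-sphere-corrected dipole kernel `D(k) = 1/3 - kz^2 / |k|^2`
#' relating a susceptibility distribution to the normalized field
#' perturbation it induces along B0.  `D` at `k = 0` is set to 0: the mean
#' (absolute) susceptibility offset is unobservable from phase, so the
#' simulated and reconstructed fields are mean-free by convention.
#'
#' @param dim integer 3-vector of array dimensions.
#' @param voxel_size_mm voxel edge lengths (mm); anisotropy tilts the
#'   k-grid, so it matters even for a "unit" kernel.
#' @param b0_axis axis index (1-3) along which the main field lies;
#'   default 3 (slice/axial axis).
#' @return real array of kernel values in `[-2/3, 1/3]`.
#' @export
dipole_kernel <- function(dim, voxel_size_mm = c(1, 1, 1), b0_axis = 3L) {
  stopifnot(b0_axis %in% 1:3)
  kg <- k_grid(dim, voxel_size_mm)
  kpar <- switch(b0_axis, kg$kx, kg$ky, kg$kz)
  d <- 1 / 3 - kpar^2 / kg$k2
  d[kg$k2 == 0] <- 0
  d
}

#' Zero-pad / crop a 3D array
#'
#' @param x 3D array.
#' @param pad non-negative integer padding per side (same on all sides).
#' @param value fill value.
#' @return padded array of dimension `dim(x) + 2 * pad`.
#' @keywords internal
pad3 <- function(x, pad, value = 0) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(value, dim = d + 2L * pad)
  out[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])] <- x
  out
}

#' @rdname pad3
#' @keywords internal
crop3 <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x) - 2L * pad
  x[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])]
}

#' Spectral Laplacian of a 3D array
#'
#' Applies the continuous-symbol Laplacian `-(2*pi*|k|)^2` spectrally.
#' Exact for band-limited fields; assumes periodic boundaries.
#'
#' @param x real 3D array.
#' @param voxel_size_mm voxel size (mm).
#' @return real array, Laplacian in units of `x` per mm^2.
#' @keywords internal
laplacian3 <- function(x, voxel_size_mm = c(1, 1, 1)) {
  kg <- k_grid(dim(x), voxel_size_mm)
  ifft3_real(fft3(x) * (-(2 * pi)^2 * kg$k2))
}

#' Inverse spectral Laplacian (zero-mean solution)
#' @keywords internal
inv_laplacian3 <- function(x, voxel_size_mm = c(1, 1, 1)) {
  kg <- k_grid(dim(x), voxel_size_mm)
  l <- -(2 * pi)^2 * kg$k2
  il <- ifelse(l == 0, 0, 1 / l)
  ifft3_real(fft3(x) * il)
}
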