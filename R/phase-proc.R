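# Phase preprocessing: dialect normalization, Laplacian unwrapping, and a
# magnitude-derived brain mask.  First stage of the reconstruction chain.

#' Wrap phase to the principal interval
#'
#' Exact wrapping via `atan2(sin, cos)`; output in `(-pi, pi]` up to
#' floating error.
#'
#' @param x phase array or vector (radians).
#' @return wrapped phase of the same shape.
#' @export
wrap_phase <- function(x) {
  out <- atan2(sin(x), cos(x))
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' Normalize stored phase to radians
#'
#' Scanner phase is exported in vendor-specific integer dialects; this
#' maps them affinely onto `(-pi, pi]`.
#'
#' * `radians`: values pass through unchanged.
#' * `signed_int`: symmetric integer range; the half-range `M` is inferred
#'   as the smallest power of two covering `max(|raw|)`, and the map is
#'   `raw * pi / M` (so -4096 of a 13-bit export maps to -pi).
#' * `unsigned_int`: range `[0, 2^b - 1]`; maps to `raw * 2*pi / 2^b - pi`,
#'   sending the midpoint to ~0.
#' * `custom_range`: affine map with `lo -> -pi`, `hi -> +pi`.
#'
#' @param raw numeric array of stored phase values.
#' @param dialect one of `"radians"`, `"signed_int"`, `"unsigned_int"`,
#'   `"custom_range"`.
#' @param range length-2 `(lo, hi)`; required for `custom_range`.
#' @return phase array in radians.
#' @export
normalize_phase <- function(raw,
                            dialect = c("radians", "signed_int",
                                        "unsigned_int", "custom_range"),
                            range = NULL) {
  stopifnot(all(is.finite(raw)))
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    radians = raw,
    signed_int = {
      m <- 2^ceiling(log2(max(abs(raw), 1)))
      raw * pi / m
    },
    unsigned_int = {
      if (any(raw < 0)) stop("unsigned_int dialect with negative values")
      b <- 2^ceiling(log2(max(raw, 1) + 1))
      raw * 2 * pi / b - pi
    },
    custom_range = {
      if (is.null(range) || length(range) != 2L)
        stop("custom_range dialect requires range = c(lo, hi)")
      if (diff(range) == 0)
        stop("custom_range of zero width")
      (raw - range[1L]) / diff(range) * 2 * pi - pi
    })
  if (!is.null(dim(raw))) dim(out) <- dim(raw)
  out
}

#' Laplacian phase unwrapping
#'
#' Solves the Laplacian unwrapping identity
#' `lap(phi_true) = cos(phi) * lap(sin(phi)) - sin(phi) * lap(cos(phi))`
#' spectrally: the right-hand side is computed from the wrapped input and
#' inverted with the spectral inverse Laplacian (zero-mean solution).  The
#' volume is zero-padded to suppress periodic wrap-around.  The additive
#' constant left free by the inverse Laplacian is fixed by the circular
#' mean of (input - raw solution) over the mask, which pins the gauge
#' reproducibly.  By default the smooth Laplacian solution is then
#' congruence-projected: `out = phase + 2*pi * round((u - phase)/(2*pi))`,
#' so the output keeps the measured phase values exactly (important over
#' steep vein phase, which the band-limited Laplacian solution smooths)
#' and uses the Laplacian solution only to resolve the wrap count.
#'
#' @param phase wrapped phase array (radians).
#' @param mask brain mask (logical array); must be nonempty.
#' @param voxel_size_mm voxel size (mm).
#' @param pad zero-padding margin per side in voxels (default 16).
#' @param congruence project onto values congruent to the input modulo
#'   2*pi (default `TRUE`); `FALSE` returns the smooth spectral solution.
#' @return unwrapped phase array (radians).
#' @export
laplacian_unwrap <- function(phase, mask, voxel_size_mm = c(1, 1, 1),
                             pad = 16L, congruence = TRUE) {
  if (missing(mask) || is.null(mask) || !any(mask))
    stop("laplacian_unwrap requires a nonempty mask")
  p <- pad3(phase, pad)
  s <- sin(p); cc <- cos(p)
  rhs <- cc * laplacian3(s, voxel_size_mm) - s * laplacian3(cc, voxel_size_mm)
  u <- crop3(inv_laplacian3(rhs, voxel_size_mm), pad)
  diff <- phase - u
  offset <- atan2(mean(sin(diff[mask])), mean(cos(diff[mask])))
  u <- u + offset
  if (congruence) u <- phase + 2 * pi * round((u - phase) / (2 * pi))
  u
}

#' Brain mask from a magnitude image
#'
#' Lightweight stand-in for a brain extraction tool: threshold at a
#' fraction of the 99th-percentile magnitude, keep the largest 6-connected
#' component, and close morphologically.
#'
#' @param magnitude non-negative 3D array.
#' @param threshold_fraction fraction of the 99th-percentile magnitude
#'   used as the threshold (default 0.4); 0 keeps the whole volume.
#' @param closing_radius radius (voxels) of the spherical closing element;
#'   0 disables closing.
#' @return logical 3D array (single connected component).
#' @export
make_mask <- function(magnitude, threshold_fraction = 0.4,
                      closing_radius = 2L) {
  stopifnot(all(magnitude >= 0))
  thr <- threshold_fraction * stats::quantile(magnitude, 0.99, names = FALSE)
  bw <- magnitude >= thr
  if (!any(bw))
    stop("empty mask at threshold_fraction = ", threshold_fraction,
         " (threshold ", signif(thr, 4), ")")
  bw <- largest_component(bw)
  if (closing_radius > 0) bw <- binary_close(bw, closing_radius)
  bw
}
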