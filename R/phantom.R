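# Susceptibility phantom: the synthetic stand-in for the study's raw MRI.
# A phantom is an ellipsoidal "brain" of uniform tissue susceptibility into
# which paramagnetic cylindrical veins of known oxygenation are rasterized;
# the forward dipole model then produces the field/phase a gradient-echo
# acquisition would see, so every reconstruction stage has a ground truth.

#' Acquisition parameters
#'
#' Container for the gradient-echo settings that convert a normalized field
#' perturbation into phase: main field strength, echo time, the proton
#' gyromagnetic ratio, and voxel geometry.  Defaults are a 3 T axial SWI
#' acquisition with TE 14 ms and 0.6 x 0.6 x 2.0 mm voxels.
#'
#' @param b0_tesla main field strength (T).
#' @param te_seconds echo time (s).
#' @param gyromagnetic_ratio_rad_per_s_per_t proton gamma (rad s^-1 T^-1).
#' @param voxel_size_mm length-3 voxel edge lengths (mm).
#' @param b0_axis array axis (1-3) parallel to B0; default the slice axis.
#' @return object of class `acquisition_params`.
#' @export
acquisition_params <- function(b0_tesla = 3.0,
                               te_seconds = 0.014,
                               gyromagnetic_ratio_rad_per_s_per_t = 267522187.44,
                               voxel_size_mm = c(0.6, 0.6, 2.0),
                               b0_axis = 3L) {
  stopifnot(b0_tesla > 0, te_seconds > 0,
            gyromagnetic_ratio_rad_per_s_per_t > 0,
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            b0_axis %in% 1:3)
  structure(list(b0_tesla = b0_tesla,
                 te_seconds = te_seconds,
                 gamma = gyromagnetic_ratio_rad_per_s_per_t,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 b0_axis = as.integer(b0_axis)),
            class = "acquisition_params")
}

#' Phase accrued per ppm of normalized field
#' @param params [acquisition_params()].
#' @return radians per ppm (gamma * B0 * TE * 1e-6).
#' @keywords internal
rad_per_ppm <- function(params) {
  params$gamma * params$b0_tesla * params$te_seconds * 1e-6
}

#' Create an empty susceptibility phantom
#'
#' Uniform tissue susceptibility inside an ellipsoidal brain mask, zero
#' outside.  The ellipsoid's semi-axes are half the grid minus a margin, so
#' the mask never touches the volume boundary.
#'
#' @param grid_shape integer 3-vector, each entry >= 16.
#' @param tissue_chi_ppm background tissue susceptibility (ppm, SI).
#' @param mask_margin_voxels clearance between mask and volume boundary.
#' @param voxel_size_mm voxel edge lengths (mm).
#' @return object of class `susceptibility_phantom` with fields `chi_ppm`,
#'   `brain_mask`, `vein_records`, `tissue_chi_ppm`, `voxel_size_mm`.
#' @export
make_phantom <- function(grid_shape, tissue_chi_ppm = 0.02,
                         mask_margin_voxels = 4L,
                         voxel_size_mm = c(0.6, 0.6, 2.0)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, mask_margin_voxels >= 0)
  small <- which(grid_shape < 16L)
  if (length(small))
    stop("grid dimension too small (< 16) on axis ",
         paste(small, collapse = ", "))
  ctr <- (grid_shape + 1) / 2
  semi <- grid_shape / 2 - mask_margin_voxels
  if (any(semi <= 1)) stop("mask margin leaves no interior")
  cg <- .coord_grid(grid_shape)
  mask <- ((cg$x - ctr[1L]) / semi[1L])^2 +
          ((cg$y - ctr[2L]) / semi[2L])^2 +
          ((cg$z - ctr[3L]) / semi[3L])^2 <= 1
  chi <- array(0, dim = grid_shape)
  chi[mask] <- tissue_chi_ppm
  structure(list(chi_ppm = chi, brain_mask = mask,
                 vein_records = list(),
                 tissue_chi_ppm = tissue_chi_ppm,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "susceptibility_phantom")
}

.coord_grid <- function(dim) {
  list(x = array(seq_len(dim[1L]), dim = dim),
       y = array(rep(seq_len(dim[2L]), each = dim[1L]), dim = dim),
       z = array(rep(seq_len(dim[3L]), each = dim[1L] * dim[2L]), dim = dim))
}

#' Add a cylindrical vein of known oxygenation
#'
#' Rasterizes an infinite cylinder (binary, by centre distance in voxel
#' index space) and paints its in-mask voxels with the susceptibility
#' offset a vein at extraction fraction `oef_true` would carry:
#' `delta_chi_do * hct * oef_true` over tissue.  This is the inversion of
#' the OEF estimator's equation at a partial-volume factor of 1, so the
#' estimator run on the phantom truth should recover `oef_true`.
#'
#' @param phantom a `susceptibility_phantom`.
#' @param point any point on the cylinder axis (voxel coordinates).
#' @param direction axis direction 3-vector (need not be normalized).
#' @param radius_voxels cylinder radius in voxel units.
#' @param oef_true true oxygen extraction fraction in `[0, 1]`.
#' @param params [oef_params()] supplying `delta_chi_do` and `hct`.
#' @return the phantom with the vein painted and a record appended
#'   (point, direction, radius, `oef_true`, `hct`, `chi_offset_ppm`,
#'   linear voxel indices).
#' @export
add_vein <- function(phantom, point, direction = c(1, 0, 0),
                     radius_voxels, oef_true, params = oef_params()) {
  stopifnot(inherits(phantom, "susceptibility_phantom"),
            length(point) == 3L, length(direction) == 3L,
            radius_voxels > 0, oef_true >= 0, oef_true <= 1)
  u <- direction / sqrt(sum(direction^2))
  d <- dim(phantom$chi_ppm)
  cg <- .coord_grid(d)
  rx <- cg$x - point[1L]; ry <- cg$y - point[2L]; rz <- cg$z - point[3L]
  dot <- rx * u[1L] + ry * u[2L] + rz * u[3L]
  dist2 <- (rx - dot * u[1L])^2 + (ry - dot * u[2L])^2 + (rz - dot * u[3L])^2
  inside <- dist2 <= radius_voxels^2
  vein <- inside & phantom$brain_mask
  if (!any(vein))
    stop("vein lies entirely outside the brain mask")
  offset <- params$delta_chi_do * params$hct * oef_true
  phantom$chi_ppm[vein] <- phantom$tissue_chi_ppm + offset
  rec <- list(point = as.numeric(point), direction = u,
              radius_voxels = radius_voxels, oef_true = oef_true,
              hct = params$hct, chi_offset_ppm = offset,
              voxels = which(vein))
  phantom$vein_records <- c(phantom$vein_records, list(rec))
  phantom
}

#' Forward dipole field of a susceptibility distribution
#'
#' Normalized field perturbation (ppm) induced along B0, computed by
#' spectral multiplication with the unit dipole kernel.  Linear in chi;
#' periodic boundaries (the phantom world is periodic by construction).
#'
#' @param x a `susceptibility_phantom` or a 3D susceptibility array (ppm).
#' @param voxel_size_mm voxel size; taken from the phantom if given one.
#' @param b0_axis axis parallel to B0 (default 3).
#' @return real 3D array, field in ppm (zero-mean by the `D(0) = 0`
#'   convention).
#' @export
forward_field <- function(x, voxel_size_mm = c(1, 1, 1), b0_axis = 3L) {
  if (inherits(x, "susceptibility_phantom")) {
    voxel_size_mm <- x$voxel_size_mm
    x <- x$chi_ppm
  }
  stopifnot(all(is.finite(x)))
  d <- dipole_kernel(dim(x), voxel_size_mm, b0_axis)
  ifft3_real(fft3(x) * d)
}

#' Harmonic polynomial background field
#'
#' Low-order polynomial field (ppm) that is harmonic everywhere, standing
#' in for shim imperfections and air/tissue interfaces far from the brain:
#' `c0 + cx*x + cy*y + cz*z` on coordinates normalized to `[-1, 1]`.
#'
#' @param dim grid dimensions.
#' @param coeffs numeric length-4 vector `(c0, cx, cy, cz)` in ppm.
#' @return 3D array in ppm.
#' @export
background_poly <- function(dim, coeffs = c(0, 0, 0, 0)) {
  stopifnot(length(coeffs) == 4L)
  cg <- .coord_grid(dim)
  nx <- 2 * (cg$x - 1) / (dim[1L] - 1) - 1
  ny <- 2 * (cg$y - 1) / (dim[2L] - 1) - 1
  nz <- 2 * (cg$z - 1) / (dim[3L] - 1) - 1
  coeffs[1L] + coeffs[2L] * nx + coeffs[3L] * ny + coeffs[4L] * nz
}

#' Background field from exterior point sources
#'
#' Field of point susceptibility sources placed outside the brain mask,
#' via the same forward dipole model.  Inside the mask the result is
#' (discretely) harmonic, which is exactly the property spherical-mean
#' background removal exploits.
#'
#' @param dim grid dimensions.
#' @param sources data.frame with voxel coordinates `x`, `y`, `z` and
#'   source strength `chi_ppm`.
#' @param voxel_size_mm voxel size (mm).
#' @param mask optional brain mask; sources inside it are rejected.
#' @param b0_axis axis parallel to B0.
#' @param sigma_voxels Gaussian width (voxels) smoothing each point
#'   source; default 1.5.  Physical background sources (air cavities,
#'   shim) are not single-voxel impulses, and the spherical-mean-value
#'   property only holds to discretization accuracy for fields that are
#'   smooth on the kernel scale.
#' @return 3D field array (ppm).
#' @export
exterior_source_field <- function(dim, sources, voxel_size_mm = c(1, 1, 1),
                                  mask = NULL, b0_axis = 3L,
                                  sigma_voxels = 1.5) {
  chi <- array(0, dim = dim)
  for (i in seq_len(nrow(sources))) {
    ix <- round(c(sources$x[i], sources$y[i], sources$z[i]))
    if (any(ix < 1) || any(ix > dim))
      stop("exterior source ", i, " lies outside the volume")
    if (!is.null(mask) && mask[ix[1L], ix[2L], ix[3L]])
      stop("exterior source ", i, " lies inside the brain mask")
    chi[ix[1L], ix[2L], ix[3L]] <- chi[ix[1L], ix[2L], ix[3L]] +
      sources$chi_ppm[i]
  }
  if (sigma_voxels > 0) {
    kg <- k_grid(dim, c(1, 1, 1))   # smoothing in index space
    chi <- ifft3_real(fft3(chi) * exp(-2 * pi^2 * sigma_voxels^2 * kg$k2))
  }
  forward_field(chi, voxel_size_mm, b0_axis)
}

#' Synthesize wrapped phase and magnitude from a field map
#'
#' Converts the normalized field (plus any background field) into
#' gradient-echo phase at the given acquisition settings, adds complex
#' Gaussian noise to the unit-magnitude signal, and wraps exactly with
#' `atan2(sin, cos)`.
#'
#' @param field_ppm 3D normalized field (ppm), e.g. from [forward_field()].
#' @param params [acquisition_params()].
#' @param mask brain mask (magnitude support).
#' @param noise_sd complex-noise standard deviation per channel, relative
#'   to the unit in-mask magnitude; 0 for noiseless.
#' @param background_ppm optional 3D background field (ppm) added before
#'   phase conversion.
#' @param seed integer seed for the noise draw (required reproducibility
#'   contract when `noise_sd > 0`).
#' @return list with `phase` (wrapped, radians, in `(-pi, pi]`),
#'   `magnitude`, and `true_phase` (unwrapped, radians).
#' @export
synthesize_phase <- function(field_ppm, params = acquisition_params(),
                             mask = NULL, noise_sd = 0,
                             background_ppm = NULL, seed = NULL) {
  stopifnot(noise_sd >= 0)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(field_ppm))
  total <- field_ppm
  if (!is.null(background_ppm)) total <- total + background_ppm
  true_phase <- rad_per_ppm(params) * total
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(true_phase)
    s <- as.numeric(mask) * exp(1i * true_phase) +
      noise_sd * complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    phase <- array(Arg(s), dim = dim(true_phase))
    magnitude <- array(Mod(s), dim = dim(true_phase))
  } else {
    phase <- wrap_phase(true_phase)
    magnitude <- array(as.numeric(mask), dim = dim(true_phase))
  }
  list(phase = phase, magnitude = magnitude, true_phase = true_phase)
}

#' Simulate a two-group ROI-mean cohort from summary statistics
#'
#' Draws per-subject regional means from independent normal distributions
#' with the per-region, per-group mean and SD of a printed summary table —
#' emulating the statistical structure (not the spatial structure) of a
#' two-group regional OEF study.
#'
#' @param spec data.frame with columns `region`, `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b` (see [cohort_spec()]).
#' @param seed integer seed; same seed, same table.
#' @param group_names length-2 character, labels for groups a and b.
#' @return data.frame with columns `subject_id`, `group`, `region`, `value`.
#' @export
simulate_cohort <- function(spec, seed = 1L,
                            group_names = c("OSA", "HC")) {
  spec <- cohort_spec(spec)
  set.seed(seed)
  out <- vector("list", 2L * nrow(spec))
  k <- 0L
  for (i in seq_len(nrow(spec))) {
    for (g in 1:2) {
      n <- spec[[c("n_a", "n_b")[g]]][i]
      mu <- spec[[c("mean_a", "mean_b")[g]]][i]
      sdv <- spec[[c("sd_a", "sd_b")[g]]][i]
      k <- k + 1L
      out[[k]] <- data.frame(
        subject_id = sprintf("%s%02d", substr(group_names[g], 1, 1), seq_len(n)),
        group = group_names[g],
        region = spec$region[i],
        value = stats::rnorm(n, mu, sdv),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Validate a cohort summary specification
#'
#' @param spec data.frame with the columns documented in
#'   [simulate_cohort()].
#' @return the validated data.frame.
#' @export
cohort_spec <- function(spec) {
  need <- c("region", "mean_a", "sd_a", "n_a", "mean_b", "sd_b", "n_b")
  miss <- setdiff(need, names(spec))
  if (length(miss)) stop("cohort spec missing columns: ",
                         paste(miss, collapse = ", "))
  if (any(spec$sd_a < 0) || any(spec$sd_b < 0)) stop("SDs must be >= 0")
  if (any(spec$n_a < 2) || any(spec$n_b < 2)) stop("group sizes must be >= 2")
  spec
}
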