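# Shared fixtures, built once per test run and cached.  Everything is
# generated in code; no binary fixtures on disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# 48^3 isotropic phantom with a single vein at OEF 0.45, plus its forward
# field -- the workhorse for inversion and OEF tests.
vein_phantom48 <- function() {
  fixture("vein48", function() {
    ph <- make_phantom(c(48, 48, 48), tissue_chi_ppm = 0.02,
                       mask_margin_voxels = 5, voxel_size_mm = c(1, 1, 1))
    ph <- add_vein(ph, point = c(24, 24, 24), direction = c(1, 0, 0),
                   radius_voxels = 2.5, oef_true = 0.45)
    list(phantom = ph, field = forward_field(ph))
  })
}

# Smooth exterior-source background field on a 96^3 grid with an
# ellipsoidal mask: harmonic inside the mask by construction.  Large
# enough for the default V-SHARP kernel schedule (largest radius 25).
harmonic_bg96 <- function() {
  fixture("bg96", function() {
    dim3 <- c(96, 96, 96)
    ph <- make_phantom(dim3, tissue_chi_ppm = 0, mask_margin_voxels = 12,
                       voxel_size_mm = c(1, 1, 1))
    src <- data.frame(x = c(4, 92, 48, 48), y = c(48, 48, 4, 48),
                      z = c(48, 48, 48, 92), chi_ppm = c(90, -75, 60, 80))
    bg <- exterior_source_field(dim3, src, c(1, 1, 1), mask = ph$brain_mask)
    list(mask = ph$brain_mask, bg = bg, phantom = ph)
  })
}

# Smooth 6*pi-peak Gaussian phase bump with its wrapped version.
phase_bump <- function(n = 48) {
  x <- seq(-1, 1, length.out = n)
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  truth <- 6 * pi * exp(-r2 / (2 * 0.25^2))
  list(truth = truth, wrapped = wrap_phase(truth), mask = r2 < 0.8)
}

expect_rel_error <- function(est, truth, tol) {
  expect_lt(abs(est - truth) / abs(truth), tol)
}
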