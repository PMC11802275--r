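test_that("make_phantom builds a masked uniform tissue volume", {
  ph0 <- make_phantom(c(64, 64, 32), tissue_chi_ppm = 0,
                      voxel_size_mm = c(1, 1, 1))
  expect_true(all(ph0$chi_ppm == 0))
  expect_gt(sum(ph0$brain_mask), 0)

  ph <- make_phantom(c(64, 64, 32), tissue_chi_ppm = 0.02,
                     voxel_size_mm = c(1, 1, 1))
  expect_true(all(ph$chi_ppm[ph$brain_mask] == 0.02))
  expect_true(all(ph$chi_ppm[!ph$brain_mask] == 0))

  # brute-force margin scan: no mask voxel within 4 voxels of the boundary
  ph4 <- make_phantom(c(32, 40, 24), mask_margin_voxels = 4,
                      voxel_size_mm = c(1, 1, 1))
  ix <- which(ph4$brain_mask, arr.ind = TRUE)
  for (ax in 1:3) {
    expect_gte(min(ix[, ax]), 5)
    expect_lte(max(ix[, ax]), dim(ph4$brain_mask)[ax] - 4)
  }

  expect_error(make_phantom(c(8, 64, 64)), "axis 1")
  expect_error(make_phantom(c(64, 64, 12)), "axis 3")
})

test_that("add_vein paints the prescribed susceptibility offset", {
  ph <- make_phantom(c(32, 32, 32), tissue_chi_ppm = 0.02,
                     voxel_size_mm = c(1, 1, 1))
  # invisible vein at OEF 0
  ph0 <- add_vein(ph, c(16, 16, 16), c(1, 0, 0), 2, oef_true = 0)
  expect_true(all(ph0$chi_ppm[ph0$brain_mask] == 0.02))

  # offset = delta_chi_do * Hct * OEF ~ 0.458 ppm at OEF 0.45, Hct 0.45
  p <- oef_params()
  ph1 <- add_vein(ph, c(16, 16, 16), c(1, 0, 0), 2.5, 0.45, p)
  rec <- ph1$vein_records[[1]]
  expect_equal(rec$chi_offset_ppm, 0.45 * 0.45 * p$delta_chi_do)
  expect_equal(rec$chi_offset_ppm, 0.458, tolerance = 1e-3)
  expect_true(all(abs(ph1$chi_ppm[rec$voxels] - (0.02 + rec$chi_offset_ppm))
                  < 1e-12))

  # two non-overlapping veins: voxel counts add exactly
  ph2 <- add_vein(ph1, c(16, 16, 24), c(0, 1, 0), 2, 0.3)
  n1 <- length(ph1$vein_records[[1]]$voxels)
  n2 <- length(ph2$vein_records[[2]]$voxels)
  all_vein <- unique(unlist(lapply(ph2$vein_records, `[[`, "voxels")))
  expect_identical(length(all_vein), n1 + n2)

  expect_error(add_vein(ph, c(2, 2, 2), c(0, 0, 1), 1, 0.4),
               "outside the brain mask")
})

test_that("vein ground-truth bookkeeping holds (single-vein contrast)", {
  fx <- vein_phantom48()
  ph <- fx$phantom
  rec <- ph$vein_records[[1]]
  tissue_ix <- setdiff(which(ph$brain_mask), rec$voxels)
  contrast <- mean(ph$chi_ppm[rec$voxels]) - mean(ph$chi_ppm[tissue_ix])
  expect_equal(contrast, rec$chi_offset_ppm, tolerance = 1e-12)
  expect_equal(rasterization_pv(ph), 1, tolerance = 1e-12)
})

test_that("dipole kernel has the analytic pointwise values", {
  d <- dipole_kernel(c(16, 16, 16), c(1, 1, 1))
  expect_equal(d[1, 1, 2], -2 / 3)           # on the kz axis
  expect_equal(d[1, 1, 9], -2 / 3)
  expect_equal(d[2, 3, 1], 1 / 3)            # in the kz = 0 plane
  expect_equal(d[5, 2, 1], 1 / 3)
  expect_equal(d[3, 3, 3], 0)                # magic angle: kz^2/|k|^2 = 1/3
  expect_equal(d[1, 1, 1], 0)                # D(0) = 0 convention
  expect_true(all(d >= -2 / 3 - 1e-12 & d <= 1 / 3 + 1e-12))
  # B0 along x moves the -2/3 values onto the kx axis
  dx <- dipole_kernel(c(16, 16, 16), c(1, 1, 1), b0_axis = 1L)
  expect_equal(dx[2, 1, 1], -2 / 3)
})

test_that("forward field is linear and matches direct circular convolution", {
  expect_true(all(forward_field(array(0, c(16, 16, 16))) == 0))

  set.seed(42)
  dim3 <- c(12, 12, 12)
  x1 <- array(rnorm(prod(dim3)), dim3)
  x2 <- array(rnorm(prod(dim3)), dim3)
  f12 <- forward_field(2 * x1 - 3 * x2, c(1, 1, 1))
  expect_equal(f12, 2 * forward_field(x1, c(1, 1, 1)) -
                    3 * forward_field(x2, c(1, 1, 1)), tolerance = 1e-10)

  # oracle: direct circular convolution with the kernel impulse response
  dim8 <- c(8, 8, 8)
  h <- forward_field(`[<-`(array(0, dim8), 1, 1), c(1, 1, 1))  # impulse at (1,1,1)
  chi <- array(0, dim8)
  set.seed(1)
  src <- cbind(sample(8, 5, TRUE), sample(8, 5, TRUE), sample(8, 5, TRUE))
  amp <- rnorm(5)
  for (i in 1:5) chi[src[i, 1], src[i, 2], src[i, 3]] <-
    chi[src[i, 1], src[i, 2], src[i, 3]] + amp[i]
  direct <- array(0, dim8)
  shift_ix <- function(n, s) ((seq_len(n) - 1 - s) %% n) + 1
  for (i in 1:5) {
    sh <- h[shift_ix(8, src[i, 1] - 1), shift_ix(8, src[i, 2] - 1),
            shift_ix(8, src[i, 3] - 1)]
    direct <- direct + amp[i] * sh
  }
  expect_equal(forward_field(chi, c(1, 1, 1)), direct, tolerance = 1e-10)

  # impulse response geometry of a paramagnetic point source:
  # (3 cos^2 theta - 1)/r^3 pattern -> positive lobes along B0 (theta = 0),
  # negative ring in the transverse plane (theta = pi/2)
  h16 <- forward_field(`[<-`(array(0, c(16, 16, 16)), 8 + 16 * 7 + 256 * 7, 1),
                       c(1, 1, 1))
  expect_gt(h16[8, 8, 9], 0)   # along B0
  expect_gt(h16[8, 8, 7], 0)
  expect_lt(h16[9, 8, 8], 0)   # in-plane ring
  expect_lt(h16[8, 9, 8], 0)
})

test_that("synthesize_phase wraps exactly and is deterministic", {
  # rad_per_ppm = 1 with these settings, so field values are phases
  acq1 <- acquisition_params(b0_tesla = 1, te_seconds = 1,
                             gyromagnetic_ratio_rad_per_s_per_t = 1e6,
                             voxel_size_mm = c(1, 1, 1))
  f <- array(0, c(16, 16, 16))
  s0 <- synthesize_phase(f, acq1)
  expect_true(all(s0$phase == 0))

  f[2, 2, 2] <- 3 * pi / 2
  s1 <- synthesize_phase(f, acq1)
  expect_equal(s1$phase[2, 2, 2], -pi / 2, tolerance = 1e-12)
  expect_true(all(s1$phase > -pi - 1e-12 & s1$phase <= pi + 1e-12))

  mask <- array(TRUE, c(16, 16, 16))
  sa <- synthesize_phase(f, acq1, mask, noise_sd = 0.05, seed = 9L)
  sb <- synthesize_phase(f, acq1, mask, noise_sd = 0.05, seed = 9L)
  expect_identical(sa$phase, sb$phase)
  expect_identical(sa$magnitude, sb$magnitude)
})

test_that("simulate_cohort reproduces the specified moments", {
  spec <- data.frame(region = "Right hemisphere",
                     mean_a = 46.99, sd_a = 6.90, n_a = 15L,
                     mean_b = 54.20, sd_b = 7.35, n_b = 16L)
  # SD 0: all subjects equal the mean
  spec0 <- transform(spec, sd_a = 0, sd_b = 0)
  co0 <- simulate_cohort(spec0, seed = 3L)
  expect_true(all(co0$value[co0$group == "OSA"] == 46.99))
  expect_true(all(co0$value[co0$group == "HC"] == 54.20))

  # determinism
  expect_identical(simulate_cohort(spec, seed = 5L),
                   simulate_cohort(spec, seed = 5L))

  # law of large numbers at n x 1000
  big <- transform(spec, n_a = 15000L, n_b = 16000L)
  cob <- simulate_cohort(big, seed = 1L)
  expect_lt(abs(mean(cob$value[cob$group == "OSA"]) - 46.99), 0.1)
  expect_lt(abs(mean(cob$value[cob$group == "HC"]) - 54.20), 0.1)

  expect_error(simulate_cohort(transform(spec, sd_a = -1)), "SDs")
  expect_error(simulate_cohort(transform(spec, n_b = 1L)), "sizes")
})
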