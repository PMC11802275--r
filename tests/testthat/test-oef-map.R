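test_that("vein detection applies the local mean + k*SD threshold", {
  # constructed VOI: 10x10x10 tissue at 0.02 ppm with a 40-voxel cylinder
  # at 0.48 ppm -> exactly the cylinder voxels detected
  chi <- array(0.02, c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  cyl <- as.matrix(expand.grid(x = 1:10, y = 5:6, z = 5:6))
  chi[cyl] <- 0.48
  bounds <- list(c(1, 10), c(1, 10), c(1, 10))
  det <- detect_veins(chi, mask, bounds, voi_grid(c(10, 10, 10)))
  expect_true(det$defined)
  expect_identical(which(det$vein), which(chi > 0.1))
  expect_identical(sum(det$vein), 40L)

  # constant VOI: SD ~ 0, no veins
  det0 <- detect_veins(array(0.02, c(10, 10, 10)), mask, bounds,
                       voi_grid(c(10, 10, 10)))
  expect_true(det0$defined)
  expect_false(any(det0$vein))

  # enormous multiplier: nothing exceeds the threshold
  detInf <- detect_veins(chi, mask, bounds,
                         voi_grid(c(10, 10, 10),
                                  threshold_sd_multiplier = 1e6))
  expect_false(any(detInf$vein))

  # VOI outside the mask: undefined, not an error
  detOut <- detect_veins(chi, array(FALSE, c(10, 10, 10)), bounds,
                         voi_grid(c(10, 10, 10)))
  expect_false(detOut$defined)
  expect_identical(detOut$reason, "voi_outside_mask")
})

test_that("delta-chi estimation is a shift-invariant two-population mean", {
  chi <- array(0.02, c(10, 10, 10))
  mask <- array(TRUE, c(10, 10, 10))
  vein <- array(FALSE, c(10, 10, 10)); vein[4:6, 4:6, 4:6] <- TRUE
  chi[vein] <- 0.48
  bounds <- list(c(1, 10), c(1, 10), c(1, 10))
  est <- estimate_delta_chi(chi, mask, bounds, vein)
  expect_equal(est$delta_chi, 0.46, tolerance = 1e-12)

  est_shift <- estimate_delta_chi(chi + 5, mask, bounds, vein)
  expect_equal(est_shift$delta_chi, est$delta_chi, tolerance = 1e-12)

  all_vein <- array(TRUE, c(10, 10, 10))
  est_deg <- estimate_delta_chi(chi, mask, bounds, all_vein)
  expect_true(is.na(est_deg$delta_chi))
  expect_identical(est_deg$reason, "no_surrounding_tissue")

  est_empty <- estimate_delta_chi(chi, mask, bounds,
                                  array(FALSE, c(10, 10, 10)))
  expect_true(is.na(est_empty$delta_chi))
  expect_identical(est_empty$reason, "no_veins")
})

test_that("the OEF equation is linear in delta-chi, P_v, and 1/Hct", {
  p <- oef_params()
  expect_identical(oef_from_delta_chi(0, p), 0)

  # solve for delta-chi at OEF 0.45, then forward-evaluate
  dchi_45 <- 0.45 * p$delta_chi_do * p$hct / p$pv
  expect_equal(oef_from_delta_chi(dchi_45, p), 0.45, tolerance = 1e-12)
  expect_equal(dchi_45, 0.0763, tolerance = 1e-3)

  p2 <- oef_params(pv = 2 * p$pv)
  expect_equal(oef_from_delta_chi(dchi_45, p2), 0.90, tolerance = 1e-12)

  expect_true(is.na(oef_from_delta_chi(NaN, p)))
})

test_that("sliding window assembles, averages overlaps, flags undefined", {
  fx <- vein_phantom48()
  ph <- fx$phantom
  m <- ph$brain_mask

  # single window covering the whole volume: constant map at that OEF
  g1 <- voi_grid(c(48, 48, 48))
  map1 <- sliding_window_oef(ph$chi_ppm, m, g1, oef_params(pv = 1))
  vals <- map1$values[m]
  expect_equal(length(unique(round(vals, 12))), 1L)
  expect_equal(vals[1], 0.45, tolerance = 0.02)
  expect_true(all(is.na(map1$values[!m])))

  # overlap-averaging consistency: windows that coincide give identical
  # values, so halving the stride leaves the non-overlap window values
  # unchanged in the per-window table
  g_no <- voi_grid(c(24, 24, 48), stride_voxels = c(24, 24, 48))
  g_half <- voi_grid(c(24, 24, 48), stride_voxels = c(12, 12, 48))
  w_no <- sliding_window_oef(ph$chi_ppm, m, g_no, oef_params(pv = 1))$windows
  w_half <- sliding_window_oef(ph$chi_ppm, m, g_half, oef_params(pv = 1))$windows
  shared <- merge(w_no, w_half, by = c("x0", "y0", "z0"))
  expect_gt(nrow(shared), 0)
  expect_equal(shared$oef.x, shared$oef.y)

  # map without any detectable vein: all-undefined plus warning
  flat <- array(0.02, dim(m))  # constant chi, no veins anywhere
  expect_warning(
    map_flat <- sliding_window_oef(flat, m, g1, oef_params()),
    "all-undefined")
  expect_true(all(is.na(map_flat$values)))

  # window_count covers every defined voxel
  expect_true(all(map1$window_count[!is.na(map1$values)] >= 1))
})

test_that("OEF map is shift-invariant and scale-equivariant in chi", {
  fx <- vein_phantom48()
  ph <- fx$phantom
  m <- ph$brain_mask
  g <- voi_grid(c(48, 48, 48))
  p <- oef_params()
  base <- sliding_window_oef(ph$chi_ppm, m, g, p)$values
  shifted <- sliding_window_oef(ph$chi_ppm + 0.3, m, g, p)$values
  scaled <- sliding_window_oef(2 * ph$chi_ppm, m, g, p)$values
  expect_equal(shifted, base, tolerance = 1e-10)
  expect_equal(scaled, 2 * base, tolerance = 1e-10)
})

test_that("regional means aggregate defined voxels per label", {
  vals <- array(NA_real_, c(12, 12, 12))
  labels <- array(0L, c(12, 12, 12))
  vals[2:11, 2:11, 2:6] <- 0.3; labels[2:11, 2:11, 2:6] <- 1L
  vals[2:11, 2:11, 7:11] <- 0.5; labels[2:11, 2:11, 7:11] <- 2L
  labels[1, 1, 12] <- 7L  # label with no defined voxels
  expect_warning(tab <- roi_means(vals, labels,
                                  names = data.frame(label = 1:2,
                                                     region = c("A", "B"))),
                 "label 7")
  expect_identical(tab$region, c("A", "B"))
  expect_equal(tab$mean_oef, c(30, 50))
  expect_identical(tab$n_defined, c(500L, 500L))

  # uniform map: every ROI mean equals the map value
  vals[] <- 0.4
  labels[labels == 7L] <- 0L
  tab_u <- roi_means(vals, labels, percent = FALSE)
  expect_true(all(tab_u$mean_oef == 0.4))

  expect_error(roi_means(vals, array(1L, c(6, 6, 6))), "grid")
})

test_that("CGS and SI unit systems give identical OEF", {
  fx <- vein_phantom48()
  ph <- fx$phantom
  m <- ph$brain_mask
  g <- voi_grid(c(48, 48, 48))
  si <- sliding_window_oef(ph$chi_ppm, m, g, oef_params())
  chi_cgs <- ph$chi_ppm * 1e-6 / (4 * pi)
  cgs <- sliding_window_oef(chi_cgs, m, g, oef_params(unit_system = "CGS"))
  def <- !is.na(si$values)
  expect_identical(which(def), which(!is.na(cgs$values)))
  expect_lt(max(abs(si$values[def] - cgs$values[def]) /
                  abs(si$values[def])), 1e-9)
})
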