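#!/usr/bin/env Rscript
# Step 3: vein-based sliding-window OEF mapping and regional means.
#
# Runs the OEF estimator (vein detection at mean + 2 SD within
# 64 x 64 x 30 windows, susceptibility contrast, OEF conversion at
# Hct 0.45) over both the ground-truth susceptibility and the step-2
# reconstruction, extracts per-vein and regional means against a simple
# two-region label volume, and writes results/oef/oef_recovery.csv.

suppressPackageStartupMessages(library(qsmoef))

out_dir <- "results/oef"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

truth <- read_nifti("results/phantom/chi_truth.nii.gz")
maskv <- read_nifti("results/phantom/mask.nii.gz")
qsm <- read_nifti("results/qsm/qsm.nii.gz")
emv <- read_nifti("results/qsm/eroded_mask.nii.gz")
veins <- readRDS("results/phantom/vein_records.rds")
vox <- truth$voxel_size_mm
mask <- maskv$data > 0.5
em <- emv$data > 0.5

grid <- voi_grid(c(64, 64, 30), stride_voxels = c(64, 64, 30))
# calibrate P_v from the phantom's rasterization geometry (= 1 for the
# binary cylinders used here), not from the estimator's own output
ph_like <- structure(list(chi_ppm = truth$data, brain_mask = mask,
                          vein_records = veins,
                          tissue_chi_ppm = 0.02, voxel_size_mm = vox),
                     class = "susceptibility_phantom")
# float32 round-trip of the truth volume can leave the geometric factor a
# hair under its exact value of 1; clamp to the valid range
p_cal <- oef_params(pv = max(1, mean(rasterization_pv(ph_like))))

map_truth <- sliding_window_oef(truth$data, mask, grid, p_cal)
map_rec <- sliding_window_oef(qsm$data, em, grid, p_cal)

rows <- do.call(rbind, lapply(seq_along(veins), function(i) {
  v <- veins[[i]]$voxels
  data.frame(vein = i, oef_true = veins[[i]]$oef_true,
             oef_truth_route = mean(map_truth$values[v], na.rm = TRUE),
             oef_recon_route = mean(map_rec$values[v], na.rm = TRUE))
}))
rows$rel_err_truth <- abs(rows$oef_truth_route - rows$oef_true) / rows$oef_true
rows$rel_err_recon <- abs(rows$oef_recon_route - rows$oef_true) / rows$oef_true
print(rows, row.names = FALSE, digits = 3)
write.csv(rows, file.path(out_dir, "oef_recovery.csv"), row.names = FALSE)

# regional means against a left/right split of the eroded mask
labels <- array(0L, dim(mask))
labels[em] <- 1L
half <- seq_len(dim(mask)[1] / 2)
labels[half, , ][em[half, , ]] <- 2L
roi <- roi_means(map_rec, labels,
                 names = data.frame(label = 1:2,
                                    region = c("right half", "left half")))
print(roi, row.names = FALSE, digits = 3)
write.csv(roi, file.path(out_dir, "roi_means.csv"), row.names = FALSE)
message("wrote oef_recovery.csv and roi_means.csv to ", out_dir)
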