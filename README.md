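# qsmoef

Quantitative susceptibility mapping (QSM) and venous oxygen extraction
fraction (OEF) analysis in R, with a fully synthetic ground-truth phantom
so that every stage is verifiable at desk scale.

## The problem

Veins carry more deoxyhemoglobin than arteries or tissue, and
deoxyhemoglobin is paramagnetic: venous blood has a higher magnetic
susceptibility than its surroundings, in proportion to how much oxygen the
tissue extracted.  Gradient-echo MRI phase encodes the field perturbation
this susceptibility induces, so from a single SWI acquisition one can
reconstruct a susceptibility map, find the veins, and read off the oxygen
extraction fraction:

    OEF = (Δχ · P_v) / (Δχ_do · Hct)

where `Δχ` is the measured susceptibility difference between venous voxels
and the surrounding tissue, `Δχ_do ≈ 4π · 0.18 ppm` (SI; `1.8e-7` in CGS
units) is the susceptibility difference between fully deoxygenated and
fully oxygenated blood per unit hematocrit, `Hct = 0.45` is the hematocrit
fraction, and `P_v ≈ 6` corrects the partial-volume dilution of the vein
signal.  Mapped region by region and compared between groups (e.g. 15
obstructive-sleep-apnea patients vs 16 controls), regional OEF becomes a
candidate physiological biomarker.

The package implements the full chain:

1. **Phantom simulator** — ellipsoidal "brain" with cylindrical veins of
   known oxygenation, forward dipole model `D(k) = 1/3 − kz²/|k|²`,
   harmonic background fields from exterior sources, exact phase wrapping,
   complex noise (`make_phantom`, `add_vein`, `forward_field`,
   `synthesize_phase`, `simulate_cohort`).
2. **Phase processing** — integer-dialect normalization onto `(−π, π]`,
   Laplacian phase unwrapping with congruence projection, magnitude-based
   brain mask (`normalize_phase`, `laplacian_unwrap`, `make_mask`).
3. **Background removal** — V-SHARP: spherical-mean-value filtering with a
   decreasing kernel schedule and TSVD deconvolution (`smv_filter`,
   `vsharp`).
4. **Dipole inversion** — thresholded k-space division plus a two-pass
   variant that reconstructs and subtracts strong sources first to reduce
   streaking (`tkd_invert`, `star_invert`).
5. **OEF mapping** — per-window vein detection at `mean + 2·SD`,
   susceptibility contrast, OEF conversion, sliding-window assembly,
   regional means against a label volume (`sliding_window_oef`,
   `roi_means`).
6. **Cohort statistics** — pooled-SD Cohen's d and the r-type effect size
   with the conventional cutoffs, normality-gated t / Mann–Whitney tests,
   χ²/Fisher, Pearson/Spearman correlation, Bonferroni
   (`cohens_d_from_summary`, `choose_and_run_test`, `report_table`).

A minimal NIfTI-1 reader/writer (`read_nifti`, `write_nifti`) is included
because no NIfTI package is assumed.

## Worked example

The `analysis/` directory is a numbered workflow over the package:

```sh
Rscript analysis/01_simulate_phantom.R    # phase/magnitude/truth -> results/phantom/
Rscript analysis/02_reconstruct_qsm.R     # unwrap -> V-SHARP -> inversion -> results/qsm/
Rscript analysis/03_oef_mapping.R         # sliding-window OEF -> results/oef/
Rscript analysis/04_group_statistics.R    # effect sizes + cohort tests -> results/stats/
```

Step 3 prints the recovery of the three phantom veins (true OEF 0.30 /
0.45 / 0.60), estimated once from the ground-truth susceptibility and once
from the full noiseless reconstruction:

```
 vein oef_true oef_truth_route oef_recon_route rel_err_truth rel_err_recon
    1     0.30            0.30           0.249      1.29e-08         0.169
    2     0.45            0.45           0.386      7.46e-09         0.142
    3     0.60            0.60           0.498      1.76e-08         0.171
```

On phantom truth the estimator is essentially exact; through the full
reconstruction the estimates stay strictly ordered with ~15% attenuation,
the physical cost of background removal and regularized inversion.

Step 4 recomputes pooled-SD Cohen's d from the published per-region OEF
summary statistics and reports, for example, `Right hemisphere: printed
1.010, recomputed 1.010`; 12 of the 15 printed regional effect sizes match
pooled-SD d to ±0.01 (the remaining three are consistent with the r-type
effect size instead, and are flagged in the output).

## Acceptance script

`scripts/acceptance.R` re-runs the headline computations from scratch
against the installed package — the effect-size reproduction from printed
summary statistics, a seeded synthetic cohort comparison, and the
end-to-end 96³ phantom reconstruction with per-vein OEF recovery — and
writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/qsm-oef-pipeline.Rmd`) describes the
model and its assumptions, every tunable parameter with units and
defaults, what the phantom does and does not emulate, and the numerical
choices (kernel schedules, truncation thresholds, gauge fixing,
tie-breaks) in detail.
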