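---
title: "From gradient-echo phase to venous oxygen extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From gradient-echo phase to venous oxygen extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qsmoef)
```

## The physical model

A spatial distribution of magnetic susceptibility $\chi(\mathbf{r})$
placed in a main field $B_0$ perturbs the field component along $B_0$.
In k-space the relation is a pointwise product with the unit dipole
kernel

$$ \delta B(\mathbf{k}) / B_0 = D(\mathbf{k})\,\chi(\mathbf{k}), \qquad
   D(\mathbf{k}) = \tfrac{1}{3} - \frac{k_z^2}{|\mathbf{k}|^2}, $$

with $k_z$ along $B_0$.  $D$ ranges over $[-2/3, 1/3]$, vanishes on the
magic-angle cone $k_z^2/|\mathbf{k}|^2 = 1/3$, and is set to $0$ at
$\mathbf{k} = 0$: an absolute susceptibility offset is unobservable from
phase, so all fields and reconstructions here are mean-free by
convention.  In real space the impulse response is the familiar
$(3\cos^2\theta - 1)/r^3$ pattern — positive lobes along $B_0$, a
negative ring in the transverse plane, for a paramagnetic source.

A gradient-echo acquisition converts the field to phase,
$\varphi = \gamma B_0 \mathrm{TE} \cdot \delta B/B_0$, observed wrapped
into $(-\pi, \pi]$.  At the defaults used throughout (3 T, TE 14 ms,
$\gamma = 2.675 \times 10^8\,\mathrm{rad\,s^{-1}\,T^{-1}}$) one ppm of
normalized field accrues about 11.2 rad, so venous susceptibility
($\sim$0.3–0.6 ppm over tissue) genuinely wraps.

Venous blood is paramagnetic relative to tissue in proportion to the
oxygen extracted.  With $\Delta\chi$ the measured vein/tissue
susceptibility difference, the extraction fraction is

$$ \mathrm{OEF} = \frac{\Delta\chi \cdot P_v}{\Delta\chi_{do} \cdot \mathrm{Hct}}. $$

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| $\Delta\chi_{do}$ | susceptibility of fully deoxygenated vs oxygenated blood per unit Hct | $4\pi \cdot 0.18$ ppm (SI) | stored as the exact SI equivalent of the CGS literature value $1.8\times10^{-7}$, so the two unit systems agree to machine precision |
| Hct | hematocrit fraction | 0.45 | global literature constant; per-subject override via `oef_params(hct=)` |
| $P_v$ | partial-volume correction | 6.0 | literature factor for clinical voxel/vessel geometry; phantom validation computes the geometric factor from the known rasterization instead |
| VOI shape | local window for vein detection | $64 \times 64 \times 30$ voxels | read as the window's voxel dimensions; configurable |
| stride | window step | half the window | overlaps resolved by unweighted mean of defined window values |
| SD multiplier | vein threshold `mean + k·SD` | 2.0 | one-sided upper threshold: veins are paramagnetic, a two-sided rule would admit diamagnetic voxels |
| `min_vein_voxels` | windows below it are undefined | 5 | a one-voxel "vein" makes $\Delta\chi$ an extreme order statistic |
| V-SHARP radii | SMV kernel schedule | 25, 20, 15, 10, 5, 3, 2, 1 (× smallest voxel edge, in mm) | typical published schedule; spheres rasterized in millimetre space so anisotropic voxels keep them physically spherical |
| TSVD threshold | deconvolution truncation | 0.05 | spectral magnitudes of $1 - \hat{K}_{r_{max}}$ below it are zeroed |
| TKD threshold | single-pass inversion | 0.10 | minimum $|D|$ retained; sign-preserving replacement below it |
| strong pass / weak pass / strong-source cut | two-pass inversion | 0.25 / 0.08 / 0.2 ppm | see below |
| B0 axis | array axis parallel to the main field | 3 (slice axis) | the dipole kernel orientation depends on it |

## The synthetic world

The phantom is an ellipsoidal volume of uniform tissue susceptibility
(default 0.02 ppm) with cylindrical veins rasterized **binary by centre
distance**: every vein voxel carries the full intravascular offset
$\Delta\chi_{do} \cdot \mathrm{Hct} \cdot \mathrm{OEF}_{true}$.  This
makes the ground truth exactly bookkeepable (voxel counts add, the
vein/tissue contrast equals the recorded offset to machine precision) at
the price of not emulating partial-volume dilution: the geometric
calibration `rasterization_pv()` therefore evaluates to 1 on these
phantoms, and the literature $P_v = 6$ is *not* exercised by the
recovery tests — it enters as a pure scale factor, which the
scale-equivariance property covers.

Background fields are produced by sources strictly outside the brain
mask — Gaussian-smoothed point susceptibility sources (default
$\sigma = 1.5$ voxels) and harmonic linear polynomials — so the field is
harmonic inside the mask, which is the property V-SHARP exploits.  The
smoothing is physical, not cosmetic: a single-voxel impulse a few voxels
outside the mask varies on sub-kernel scales where the *discrete*
spherical-mean property fails (measured residuals of tens of percent),
whereas smooth sources at realistic distance leave $(I-\mathrm{SMV})$
residuals of $\sim 0.3\%$.  Air/tissue interfaces and shim fields are
smooth at 0.6 mm resolution.

Noise, when requested, is complex Gaussian added to the unit-magnitude
signal before taking the phase, so phase noise scales as 1/SNR.  Cohort
tables are independent normal draws per region and group from printed
summary statistics; they emulate the statistical structure (means, SDs,
group sizes) but not inter-regional correlation within subjects.

A green phantom test therefore establishes that the chain inverts its
own forward model within stated budgets.  It does not establish accuracy
on real data, where flow effects, non-dipolar sources, vessel
orientation distributions, partial volume and physiological noise all
enter.

## Numerical choices

**Unwrapping.**  The Laplacian identity
$\nabla^2\varphi = \cos\varphi\,\nabla^2\sin\varphi -
\sin\varphi\,\nabla^2\cos\varphi$ is evaluated spectrally after
zero-padding (default 16 voxels per side) and inverted with the spectral
inverse Laplacian, whose $\mathbf{k}=0$ component is set to zero.  The
free additive constant is fixed by the circular mean of (input − raw
solution) over the mask.  The band-limited solution alone smooths the
very steep phase at vein cores (errors up to $\sim$1 rad on our
phantoms), so by default the result is congruence-projected,
$\varphi + 2\pi\,\mathrm{round}((u - \varphi)/2\pi)$: the measured
values are kept exactly and the spectral solution only resolves the wrap
count.  On noiseless phantoms this makes unwrapping exact; under heavy
noise the rounding can misfire where the spectral error exceeds $\pi$,
and `congruence = FALSE` returns the smooth solution.

**V-SHARP.**  Each voxel gets $(I - \mathrm{SMV}_r)$ with the largest
radius in the schedule whose sphere fits inside the mask there; the
combined high-pass field is deconvolved by $1 - \hat{K}_{r_{max}}$ with
TSVD truncation, and voxels where not even the smallest sphere fits are
excluded (the eroded mask).  Truncation zeroes the lowest spatial
frequencies, which is what residually attenuates extended vein fields
($\sim$15% in the recovery experiment); larger maximum radii reduce the
loss, which is why validation phantoms are sized to admit the full
default schedule.  Note that $|1-\hat K|$ ranges up to about 2, so a
truncation threshold of 1 does not annihilate the output; thresholds are
restricted to $(0,1)$.

**Inversion.**  TKD divides by $D$ where $|D|$ exceeds the threshold and
by $\mathrm{sign}(D)\cdot t$ elsewhere (sign-preserving, with
$\mathrm{sign}(0) = +1$, chosen over zeroing to reduce ringing and keep
results bit-reproducible).  The two-pass variant substitutes closed-form
TKD passes for the published two-level regularized solvers: pass 1 at
threshold 0.25 keeps voxels with $|\chi| \ge 0.2$ ppm, and because heavy
regularization underestimates amplitude, the strong component is
rescaled by the least-squares fit of its forward field to the input
before subtraction (without this the subtraction residual is $\sim$18%
of the input field; with it $\sim$5%).  Pass 2 inverts the residual at
threshold 0.08.  This preserves the strong-source-separation mechanism
with an oracle-testable inner solver; it is a variant, not a
re-implementation of any specific published solver.

**OEF windows.**  Vein detection recomputes the local threshold per
window (that is what a *local* threshold means); windows with fewer than
27 in-mask voxels, fewer than `min_vein_voxels` detections, no remaining
tissue, or (by default) negative $\Delta\chi$ are flagged undefined —
never silently zero.  Degenerate windows with SD below machine tolerance
return no veins.  Overlapping defined windows are averaged unweighted;
`window_count` records coverage.  OEF is a fraction internally and
percent at the ROI/reporting layer.

**Units.**  Everything internal is ppm, SI.  `oef_params(unit_system =
"CGS")` accepts susceptibilities in raw CGS units with
$\Delta\chi_{do} = 1.8\times10^{-7}$; since the stored SI default is
exactly $4\pi$ times the CGS value, consistent conversion of the
susceptibility volume yields identical OEF to floating precision.

**Statistics.**  The normality gate is a one-sample Kolmogorov–Smirnov
test against a normal with the sample's own mean and SD — the common
statistical-package behaviour, acknowledged to be conservative as a
gate since the reference distribution ignores parameter estimation.
Groups passing at $\alpha = 0.05$ get the pooled-variance t-test
(pooled, not Welch, because the published effect sizes match pooled-SD
Cohen's d; Welch is available); otherwise Mann–Whitney, exact for groups
of ≤ 25 without ties, else the normal approximation with tie
correction.  Both effect sizes are always reported and labelled — d
from the raw samples, r as $\sqrt{t^2/(t^2+\mathrm{df})}$ or
$|Z|/\sqrt{N}$ — because published tables mix the two conventions, and
several printed values are only consistent with r.  The 2×2 rule is
chi-square unless an expected cell is below 5 *or* an observed cell is
zero, in which case Fisher's exact test.  Bonferroni is
$\min(1, m\,p)$.

## Known limitations

* Laplacian unwrapping assumes the true phase is smooth on the voxel
  scale except at veins; pathological wrap densities (very long TE,
  very strong sources) can defeat the congruence rounding.
* V-SHARP attenuates extended low-frequency local fields; regional OEF
  from reconstructed maps is accordingly biased low by $\sim$15% on our
  phantoms.  Group *differences* are less affected since the
  attenuation is common to both groups.
* The two-pass inversion is a TKD-based variant; no equivalence with any
  particular published solver's output is claimed.
* The phantom's binary veins do not exercise the partial-volume factor;
  $P_v$ validation on anti-aliased vein models would require a
  sub-voxel forward model.
* The cohort simulator draws regions independently; analyses that rely
  on within-subject correlation across regions (e.g. the published
  per-subject correlation tables) need real subject-level data, which
  is not published.
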