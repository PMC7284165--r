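---
title: "Models and methods behind hippodwi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hippodwi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hippodwi` simulates diffusion-weighted MR microscopy of fixed hippocampal
sections in the unilateral-kainate mouse model of mesial temporal lobe
epilepsy, and reproduces the region-wise quantitative workflow used on such
data: voxel-wise diffusion tensor metrics, spherical-harmonic ADC profiles,
and a battery of orientation, group-difference and diffusion–histology
statistics. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and what the synthetic data can and
cannot establish.

## The digital phantom

A slice is a 2D grid (default 102 × 128 voxels at 0.04 mm in-plane,
mirroring a 12.8 mm × 10.2 mm field of view scaled to desk size). Rows
index the dorso-ventral (y) axis, columns the left–right (x) axis; in-plane
orientations are axial angles in degrees counterclockwise from +x, modulo
180°, with 0-based voxel indexing.

**Geometry.** Five regions are rendered as a stylized hippocampus: an outer
C-shaped CA1 pyramidal band continuing into CA3, the CA1 stratum radiatum
just interior to CA1, a V-shaped dentate-gyrus granule cell layer (GCL),
and the hilar wedge between the GCL blades, all on a saline background.
The real regions are delineated manually on histology; for the statistics
tested here any geometry that preserves region adjacency, region areas of
the right order, and the orientation structure suffices, so an
arc-and-wedge parameterisation was chosen over an atlas. Band widths scale
with grid size. The GCL band width is multiplied by a dispersion factor
(granule cell dispersion): 1 in controls, up to 2 at full ipsilateral
severity. `measure_gcl_width()` recovers the width as band area divided by
centerline length, using the analytic centerline of the generated V; for
external label maps the centerline length falls back to the band's
principal-axis extent, which is exact for straight bands and approximate
for curved ones.

**Orientations.** Each tissue voxel draws an axial orientation from a von
Mises distribution on doubled angles: φ ~ vonMises(2μ, κ), θ = φ/2 mod
180°. The doubling construction is the standard way to put a unimodal
distribution on axes rather than directions — dendrites and axons have no
polarity. Region means follow the layered architecture: 90° (dorso-ventral
dendrites) in CA1 and the GCL, 45° in CA3, 0° (left–right mossy fibers and
Schaffer collaterals) in the hilus and stratum radiatum. The within-region
concentrations (κ = 20 in CA1/CA3, 30 in the GCL, 10 in the hilus, 15 in
srCA1) are calibration choices, not measured values: real tissue curvature
means the nominal angles are only approximate, and no dispersion value is
available to copy. They were fixed once so that region-level orientation
tests on a single cohort are decisively significant in controls while
κ = 0 (uniform axes, used for regions that lose their coherent dendritic
scaffold) is decisively non-significant.

**Tensors.** Each voxel gets D = λ⊥ I + (λ∥ − λ⊥) u uᵀ with the principal
axis u in-plane at the voxel's orientation; background voxels get an
isotropic saline-like tensor (trace/3 = 2.0 × 10⁻³ mm²/s). Principal axes
are kept in-plane: the quantified measures are in-plane, and through-plane
structure would only dilute them; the z-eigenvalue equals λ⊥. Baseline
diffusivities put the regional mean diffusivity near the fixed-tissue scale
of 0.5 × 10⁻³ mm²/s (λ∥ 0.8–1.0 × 10⁻³, λ⊥ 0.2–0.4 × 10⁻³ mm²/s).

**Density coupling.** A cell-density proxy (arbitrary units, emulating
background-subtracted DAPI intensity) is generated per voxel from region
baselines, and the perpendicular diffusivity is tied to it:
λ⊥(voxel) = a_MD − b_MD · density(voxel), with defaults a_MD = 0.7 × 10⁻³
mm²/s and b_MD = 0.5 × 10⁻³ mm²/s per density unit. Denser tissue thus
diffuses less and, in layered regions, appears more anisotropic — the
mechanism that makes density–MD and density–FA correlations recoverable
from the simulated images. The region baselines were chosen on the line
λ⊥ = a_MD − b_MD · baseline, so control slices sit at their nominal
diffusivities whether coupling is on or off; setting b_MD = 0 decouples
density from the signal entirely and serves as the null for correlation
calibration.

**Condition effects and severity.** Epileptic pathology is parameterised by
a per-slice severity scalar s. Ipsilateral slices draw s uniformly on
[0.5, 1] per animal — pathological alterations vary across epileptic
animals, and this slice-level spread is what creates recoverable
*intra-group* correlations; a contralateral slice from the same animal
receives 0.4 s, applied to CA1 only, since only partial CA1 involvement
spreads to the non-injected side. At full severity the defaults are:
density loss of 65% in CA1, 55% in CA3, 35% in the GCL, 25% in the hilus,
30% in srCA1; λ∥ gains of +35% in the GCL and +60% in the hilus (mossy
fiber sprouting increases coherent axonal content); orientation
concentration overridden to κ = 0 in ipsilateral CA1 and CA3 (loss of the
pyramidal dendritic scaffold) and κ = 6 in contralateral CA1. These
magnitudes are invented defaults — the source observations are directions
and significance flags, not effect sizes — chosen once to reproduce that
qualitative pattern at the 6/9/6 cohort size, and all are exposed in the
configuration. Slice-level multiplicative jitter (sd 4% on densities,
~2.7% on diffusivities) supplies the within-group biological variability
that keeps group comparisons honest; per-voxel density noise (sd 0.03) does
the same within regions.

## Acquisition simulation

Signals follow the mono-exponential tensor model S = S0 · exp(−b gᵀDg)
over a single-shell scheme: 60 directions at b = 1000 s/mm² plus 6 b = 0
volumes by default. Directions are generated by electrostatic repulsion of
antipodal pairs (fixed 400 iterations, seeded, minimum pairwise angle
comfortably above 10° at n = 60) because the original gradient table is not
published. The b = 1000 choice for fixed tissue trades diffusion contrast
for SNR: at D = 0.5 × 10⁻³ mm²/s, `snr_gain()` and `contrast_loss()` give
+64.9% signal and −17.6% contrast sensitivity |∂S/∂D| relative to
b = 2000 s/mm² — the package reads "contrast" as that sensitivity, which
reproduces the quoted trade-off; a two-tissue signal-difference definition
is the noted alternative. Magnitude noise is Rician,
S′ = √((S+ε₁)² + ε₂²), with σ = S0/SNR defined against the tissue b0
level; the default SNR 15 sits mid-way in the 11–22 range reported for
such acquisitions. The phantom's saline background carries a reduced b0
factor (0.6) as a proton-density/T2 surrogate so that b0-based masking is
well posed — the simulator models no relaxation otherwise.

## Estimation

**Tensor fit.** Per voxel, weighted least squares on log-signals: y_i =
ln(S0/S_i) against design rows b(gx², gy², gz², 2gxgy, 2gxgz, 2gygz), with
weights S_i² — the standard one-pass WLS for log-transformed magnitude
data, adequate at SNR ≥ 10; no estimator was named for the original
analysis, and iterative reweighting adds nothing at this noise level. The
b0 volumes are averaged into the reference (the combination rule is
likewise unstated; the mean is the standard choice). Signal ratios are
clamped to (10⁻⁶, 1] before the log, with clamped voxels flagged; tensors
with negative eigenvalues are projected to positive semidefinite and
counted rather than refit (rare at this diffusivity scale). Background
masking uses Otsu's threshold on the mean b0 image, standing in for manual
masking. FA, MD and the primary in-plane orientation θ = atan2(e1y, e1x)
mod 180° come from the eigendecomposition; θ is reported axially because
the orientation hypotheses (90°/45°/0°) are only well posed for apolar
structures, and is masked where λ₁ ≈ λ₂ (within 10⁻¹²) or the principal
axis has no in-plane component.

**ADC profiles.** Per-direction ADC = −ln(S/S0)/b samples are fit with a
real even-order spherical harmonic basis (default order 4, 15
coefficients — the standard HARDI choice for 60 directions; the original
order is unstated and the knob is exposed). Even orders suffice because
ADC profiles are antipodally symmetric; order 2 spans quadratic forms
exactly, which makes the SH and tensor routes mutually consistent oracles
on noise-free data and is exploited by the test suite. No
Laplace–Beltrami regularisation is applied by default: profile noise is
handled by region averaging, and a regularisation weight would add a
tuning parameter the analysis does not need. The profile is evaluated at
the dorso-ventral (0,1,0) and left–right (1,0,0) axes to give dvD, lrD and
dvlr_ratio = dvD/lrD (ratio masked where lrD < 10⁻⁶ mm²/s). Axis values
are computed per voxel and then averaged within regions (voxel-first);
fitting one profile to the region-mean ADC is the ambiguous alternative,
available by fitting `fit_sh()` to region-averaged samples directly.

## Statistics

The unit of analysis is the slice: per-slice region means enter all tests,
matching per-section reporting. The workflow is:

* **V-test** for orientation non-uniformity against the hypothesized
  direction per region and group, on axially doubled angles
  (V = Σcos(φᵢ−φ₀), u = V√(2/n), one-sided normal p). The doubling is
  essential and documented prominently because orientations are
  180°-periodic; an un-doubled variant exists behind the `axial` flag. The
  normal approximation is standard for n ≥ 5; exact small-n tables are out
  of scope. Orientation samples are capped at 200 voxels per region per
  slice so the pooled test is not driven to arbitrary power by voxel count.
* **One-way ANOVA + Tukey HSD** across groups per region and parameter
  (and across regions within controls), via `aov()`/`TukeyHSD()`.
* **Paired t-tests** between ipsilateral and contralateral values of the
  same animal, emulating within-slice side comparisons; zero-variance
  degenerate pairs are flagged rather than erroring.
* **Pearson correlations** between diffusion parameters and the histology
  proxies (region densities, GCL width), pooled and ipsilateral-only.

No multiple-testing correction is applied by default, mirroring the single
p < 0.05 threshold of the emulated analysis; a Bonferroni option exists in
`build_report()`. Mixed-effects modelling of repeated slices per animal is
a known limitation: slices are pooled, as in the emulated workflow.

## Reproducibility and problem sizes

A master seed derives every per-slice and per-stage seed through a fixed
integer hash, so cohorts are bit-identical across runs and platforms. The
package's own validation uses: 50 seeded cohorts (full pipeline at 6/9/6,
SNR 15) for the orientation and group-difference pattern-recovery rates;
100 ipsilateral-only cohorts with b_MD = 0 for the correlation null
calibration; 1000 replicates of n = 10⁴ uniform angles for V-test size;
and 10⁵ samples for the Rician moment checks. The acceptance script
reports the same quantities at 30 pattern cohorts and 60 null cohorts —
sizes chosen so a complete from-scratch rerun stays comfortably
interactive while keeping Monte-Carlo error on rate estimates near the
percent level.

## What the phantom does and does not establish

The generator reproduces the statistical structure the analysis assumes —
region adjacency, axial orientation families, fixed-tissue diffusivity
scale, Rician noise at realistic SNR, cohort sizes, severity-coupled
density and diffusivity — so green tests establish that the estimators and
tests recover known structure at study scale. It does not render realistic
anatomy (no curvature-following orientation fields, no partial-volume
boundaries), models no relaxation, eddy currents or distortion, generates
in-plane tensors only (a through-plane tilt is deliberately absent from
defaults), and its condition effect sizes are constructed, not measured.
Agreement of the phantom pipeline with published tissue values therefore
cannot be claimed beyond the direction/significance patterns; the exact
p-values reported for real tissue are not reproducible at desk scale and
are not targets.
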