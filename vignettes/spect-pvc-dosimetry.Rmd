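---
title: "Partial-volume correction and lesion dosimetry for quantitative Lu-177 SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial-volume correction and lesion dosimetry for quantitative Lu-177 SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectpvc)
```

## The problem

Quantitative Lu-177 SPECT underpins patient-specific dosimetry in
radioligand therapy (PSMA- and somatostatin-receptor-targeted treatments),
but its spatial resolution — 5 to 25 mm full width at half maximum (FWHM)
depending on collimation and reconstruction — is coarse relative to many
lesions. Activity spills out of small structures (and background spills in),
so measured concentrations and hence absorbed doses are biased low: the
partial-volume effect (PVE). This package implements, end to end and with a
synthetic data generator standing in for the scanner and the patients, a
phantom-calibrated workflow for studying two PVE-correction strategies for
lesion dosimetry:

* **OR** — the original (uncorrected) reconstruction;
* **OR+LRD** — Richardson–Lucy deconvolution applied to each reconstructed
  volume as a post-processing step;
* **OR+RC** — the uncorrected lesion dose scaled by a volume-derived
  recovery-coefficient correction from a phantom-fitted curve.

## The forward model and the synthetic data

Real inputs (projection data, OSEM reconstruction, CT, clinical cohorts)
are out of scope; the generator replaces them with an image-space surrogate:

1. **Digital NEMA IEC body phantom** (`nema_phantom_spec`,
   `generate_phantom`): six spheres of 0.5–26.5 mL (diameters 10–37 mm) on
   the standard 114.4 mm coplanar ring inside a simplified elliptical-cylinder
   body compartment (semi-axes 110 × 90 mm, height 180 mm; the physical
   phantom's lung insert is omitted since no analysis uses it), filled at
   237:30 kBq/mL (the conventional "8:1" fill; the exact ratio is 7.9).
   Sphere edges are painted with fractional occupancies computed from an
   exact chord integral along z and 4× in-plane supersampling, which
   conserves total activity against the analytic volumes to < 0.5%. Four
   spherical background regions (radius 15 mm) sit azimuthally opposite the
   largest insert, 55 mm below the sphere plane — the physical measurement
   protocol does not specify background-region geometry, so this placement
   (far from every insert, deep in the background) is a documented choice of
   the digital phantom.
2. **Pseudo-reconstruction** (`simulate_reconstruction`): convolution with
   an isotropic 3D Gaussian point-spread function (PSF), optionally composed
   with a Poisson noise model. The default noise order draws Poisson counts
   on the unblurred grid and then smooths (`poisson-then-blur`), which
   produces the spatially correlated noise texture of reconstructed SPECT.
   The calibration scalar (0.003 counts per kBq/mL per voxel) was fixed so
   that the background coefficient of variation is ≈ 0.36 at the reference
   resolution — the 0.3–0.5 range implied by measured phantom
   signal-to-noise ratios. Noise is unbiased, so seed-averaged region means
   converge to the noiseless values.
3. **Synthetic cohort** (`cohort_spec`, `simulate_cohort`): virtual patients
   with 1–8 spherical lesions each, log-normal volumes (median 4 mL,
   occasionally tens of mL, truncated to 0.5–80 mL), tumor-to-background
   ratio (TBR) normal with mean 9.2 (defined at the first imaging time,
   truncated at 2), lesion effective half-lives normal around 60 h (truncated
   to [24 h, 160.8 h] so effective decay is never slower than physical
   Lu-177 decay), background washing out from 30 kBq/mL at t = 0 with a 50 h
   effective half-life, imaging at 24/48/72 h, injected activity
   ≈ 7308 ± 132 MBq. Every voxel's true time course is exactly
   monoexponential, and all ground truth is retained.

**What the generator does not emulate.** Collimator-distance-dependent
resolution, attenuation, scatter, reconstruction convergence artifacts,
irregular lesion shapes, uptake phases, and inter-timepoint misregistration.
Passing tests therefore demonstrate the correctness and internal consistency
of the correction machinery under a known Gaussian blur — not clinical
accuracy on real scanners. One concrete consequence, discussed below, is
that recovery coefficients under the pure-Gaussian surrogate are lower than
those measured on a real resolution-modelled reconstruction at the same
nominal resolution.

### Why cohort lesions are painted voxel-aligned

Phantom spheres are painted fractionally (conserving activity); cohort
lesions are instead painted *binary* — every voxel of the lesion's hard mask
carries the full lesion concentration. At 4.8 mm voxels, a fractionally
painted few-mL lesion measured through a hard mask is biased low by 5–13%
purely by voxelization, which would contaminate ground-truth recovery tests:
with binary painting, a noiseless unblurred measurement reproduces the
configured TBR and the analytic absorbed dose exactly, so every downstream
deviation is attributable to blur, noise, or the correction under test.

## PSF calibration: matched-filter resolution analysis

`run_mfa` estimates the effective system resolution by blurring the known
ground truth with candidate Gaussians (σ swept over an inclusive grid,
default 0–48 mm in 0.48 mm steps) and minimizing the root-mean-squared
error against the reconstruction over the voxels of the four largest
spheres (2.6–26.5 mL; the 0.5 and 1.2 mL spheres are invisible at SPECT
resolution and excluded throughout). Ties break toward smaller σ. Because
the default step (0.48 mm) does not divide typical resolutions exactly,
`refine_sigma` adds a parabolic interpolation through the three RMSE samples
around the grid arg-min; both the raw and refined values are reported, and
downstream stages take σ as explicit configuration (default 6.0 mm,
FWHM 14.1 mm). On noiseless self-consistency runs the generating σ ∈ {3, 6,
9} mm is recovered within one grid step (refined: within 0.1 mm); with the
default noise the mean recovery over 10 seeds stays within two steps.

## Richardson–Lucy deconvolution

With `d` the observed volume, `P` the normalized Gaussian kernel and
`P~` its reflection, `deconvolve` iterates

    u_{k+1} = u_k * [ ( d / max(u_k ⊗ P, ε) ) ⊗ P~ ]

* **Initialization.** The default is a uniform constant (the mean of `d`),
  matching the widely used reference implementation. Its signature is that
  the first iterate equals `d ⊗ P` (the constant cancels in the ratio), so
  sphere recovery coefficients *drop below* the uncorrected values at
  iteration 1 before climbing past them — exactly the progression seen in
  the phantom iteration table. An `"observed"` initialization (`u_0 = d`) is
  provided for flux-conservation use; with it, total activity is preserved
  to well under 0.5% per iteration for interior objects.
* **Numerics.** The division is guarded by ε = 1e-12 (ratios where the
  re-blurred estimate falls below ε contribute 0); negative input voxels are
  clipped to zero with a warning; non-negativity is preserved by the
  multiplicative update. All convolutions share the package's zero-padding
  contract (separable compiled path; identical to the FFT path to 1e-12 and
  to a direct triple-loop oracle to 1e-10). `n_iter = 0` returns the input;
  σ = 0 is an exact fixed point. The update agrees with an independent
  reference implementation (scikit-image's `richardson_lucy`, constant-0.5
  initialization, no clipping) to better than 1e-5 on a 32³ random volume
  after 4 iterations.
* **Iteration choice.** `iteration_sweep` applies 1…k iterations to the
  noisy phantom reconstruction and tabulates per-sphere recovery coefficient
  (RC) and signal-to-noise ratio (SNR): RCs rise monotonically with
  iteration while the largest sphere's SNR falls monotonically from noise
  amplification, and the reference configuration adopts 4 iterations as the
  knee of that trade-off. On the noiseless matched-PSF phantom, RMSE to
  ground truth decreases monotonically over at least the first 10
  iterations.

## Recovery coefficients and the volume-dependent correction

`compute_rc` divides the mean measured concentration in each known-volume
sphere VOI (hard mask from ground-truth geometry, never re-segmented) by the
true fill concentration. `compute_snr` uses the background-subtracted form
`(mean_sphere − mean_bkg) / SD_bkg` with mean and population SD pooled over
the voxels of all four background regions; the measurement protocol never
prints its SNR formula, so the unsubtracted variant is available behind
`subtract_background = FALSE` for sensitivity analysis.

Volume dependence is modelled by the two-parameter sigmoid

    f_RC(V) = 1 − (1 + (V/b)^y)^(−1)

fitted by bounded least squares (`stats::nls`, port algorithm, positivity
bounds, deterministic initialization b = median volume, y = 1). The curve
passes through 0.5 at V = b, rises strictly with volume for b, y > 0, and
approaches full recovery only slowly at large volumes. `rc_correction_factor`
returns 1 / f_RC(V), the multiplicative OR+RC correction — a continuous,
volume-derived factor rather than nearest-sphere lookup. Generating-parameter
recovery from noiseless samples is exact to 1e-4, and the fit is
scale-consistent (scaling all volumes by c scales b by c and leaves y
unchanged).

## Dosimetry

* **Segmentation** (`segment_lesion`): region-growing threshold segmentation
  on the first uncorrected timepoint — a regional maximum is located within
  15 mm of the seed, the threshold is 0.4 × that maximum (fixed-fraction
  mode; an absolute-concentration mode covers SUV-style workflows), and the
  6-connected supra-threshold component containing the maximum is kept. The
  proprietary gradient tool used clinically is not reproducible; masks are
  fixed on OR for all three arms, as in the study design. Lesions whose
  threshold falls below the background level grow without bound; the cohort
  driver excludes segmentations larger than 150 mL as "non-visible",
  mirroring the clinical inclusion rule that lesions must be visible on
  SPECT.
* **TBR** (`measure_tbr`): four copies of the lesion mask are placed just
  outside the lesion along ±x and ±y; TBR is the lesion mean over the average
  of the four copy means.
* **Time–activity fitting** (`fit_tac`): voxel-wise log-linear least squares
  of a monoexponential over the voxel's positive samples. Fitted decay
  constants at or below the floor (default: physical Lu-177 decay,
  ln 2 / 6.7 d) are refitted with the decay fixed at the floor and flagged;
  voxels with fewer than two positive samples are excluded (zero
  time-integrated activity). The floor prevents noise-induced non-decaying
  voxel fits from producing divergent integrals.
* **Time-integrated activity** (`integrate_tia`): the analytic 0→∞ integral
  `A0 · V_voxel / λ_eff`, converted to Bq·h per voxel. No trapezoidal
  head/tail handling — the clinical software's integration scheme is
  unpublished, so the analytic monoexponential integral (the fitted model's
  own integral) is used.
* **Dose kernel** (`default_lu177_kernel`, `convolve_dose`): voxel S-value
  convolution. The default kernel is local deposition: the mean electron
  (beta + conversion + Auger) energy per Lu-177 decay, 147.9 keV, deposited
  entirely in the source voxel of unit-density water (central element
  `E · 3600 / m_voxel` Gy per Bq·h); photon cross-dose is omitted. Published
  voxel S-value tables can be dropped in via a plain-text CSV
  (`read_dose_kernel`), since the study's own kernel values are not printed.
* **Comparison** (`compare_doses`): per lesion, mean absorbed dose per unit
  injected activity (Gy/GBq) under OR and OR+LRD, with OR+RC defined — by
  construction — as OR × 1/f_RC(segmented volume). Percent differences use
  OR as the denominator: `100 · |AD_x − AD_OR| / AD_OR` (the clinical
  report's exact formula is unstated; this definition is documented and
  symmetric in sign via the absolute value).

## Problem sizes

The reference grid is 128³ voxels at 4.8 mm isotropic (the standard pixel
size for a 128-matrix medium-energy acquisition; voxel volume 0.1106 mL,
small against the smallest analyzed sphere). The acquisition matrix is known
but the reconstructed voxel size is an assumption, exposed as configuration.
The package's own analyses, tests, and the acceptance script run the phantom
on a compact 56 × 48 × 48 grid at the same 4.8 mm spacing (which holds the
entire phantom with ≥ 4σ margins, so zero-padding is immaterial) and the
cohort on 64 × 64 × 48; the matched-filter sweeps in the test-suite cover
0–19.2 mm, which brackets all generating resolutions used there. These are
problem-size choices of the analyses; all defaults remain configurable.

## Known limitations

* The forward model is a stationary, isotropic Gaussian in image space. A
  real resolution-modelled OSEM reconstruction partially restores edges, so
  its measured sphere recovery at a matched nominal resolution is *higher*
  than the Gaussian surrogate's: the surrogate yields ≈ 0.65–0.67 for the
  26.5 mL sphere at σ = 6.0 mm versus 0.75 reported from a physical
  measurement at the same nominal FWHM. Directional and ordering conclusions
  transfer; absolute recoveries do not.
* OR+RC assumes the phantom's sphere-to-background ratio and spherical
  geometry apply to every lesion; lesion-specific geometry and TBR are known
  failure modes of RC correction and are visible in the synthetic cohort as
  residual spread.
* The local-deposition kernel ignores photon cross-dose (a few percent for
  Lu-177 at these voxel sizes) and charged-particle transport across voxel
  boundaries.
* Absorbed-dose magnitudes in the synthetic cohort are tied to the
  configured background concentration scale, not calibrated to clinical
  uptake; compare arms, not absolute Gy/GBq, against clinical tables.
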