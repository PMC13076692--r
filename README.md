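# spectpvc

Partial-volume correction and lesion dosimetry for quantitative Lu-177
SPECT, built around a fully synthetic study: a digital NEMA IEC body
phantom and a virtual patient cohort with known monoexponential kinetics
replace the scanner and the clinic, so every correction step can be tested
against ground truth.

## Who this is for

Medical-physics and nuclear-medicine researchers who want a reproducible,
scriptable sandbox for the classic lesion-dosimetry question: *how much
absorbed dose does the partial-volume effect hide, and how much of it do
image-based corrections recover?* The package compares three arms on the
same data:

| arm | meaning |
|-----|---------|
| OR | original (uncorrected) reconstruction |
| OR+LRD | OR post-processed by Richardson–Lucy deconvolution |
| OR+RC | OR lesion doses scaled by a phantom-fitted, volume-derived recovery correction |

## The model in brief

The system point-spread function is an isotropic 3D Gaussian with standard
deviation σ (FWHM = 2√(2 ln 2) σ; the reference configuration is σ = 6.0 mm,
FWHM 14.1 mm). σ is calibrated by **matched-filter resolution analysis**:
blur the known phantom ground truth with candidate Gaussians and take the σ
minimizing the RMSE against the reconstruction over the four largest
spheres.

**Richardson–Lucy deconvolution** then iterates, from a uniform-constant
initialization,

```
u_{k+1} = u_k · [ ( d / (u_k ⊗ P) ) ⊗ P̃ ]
```

with `d` the observed volume and `P` the Gaussian kernel; four iterations
are adopted from the recovery/noise trade-off on the phantom.

**Recovery coefficients** RC(V) = measured/true concentration in
known-volume spheres are modelled by

```
f_RC(V) = 1 − (1 + (V/b)^y)^(−1)
```

and OR+RC multiplies an uncorrected lesion dose by 1 / f_RC(V).

**Dosimetry** is voxel-wise: monoexponential time–activity fits over the
24/48/72 h series (log-linear least squares, effective decay floored at
physical Lu-177 decay ln 2 / 6.7 d), analytic time-integrated activity
A₀/λ_eff, and convolution with a voxel S-value kernel (default: local
deposition of the 147.9 keV mean electron energy per decay).

## Worked example

```r
library(spectpvc)

# phantom half: generate, pseudo-reconstruct, calibrate sigma, sweep
# iterations, fit the recovery curve
phantom <- run_phantom_study(phantom_study_config(mfa_stop = 19.2))
phantom$mfa
#> matched-filter analysis: 41 sigmas in [0, 19.2] mm
#>   best sigma 6.240 mm (FWHM 14.69 mm), RMSE 19.998 over 414 voxels
phantom$rc_curve
#> recovery curve f_RC(V) = 1 - (1 + (V/b)^y)^-1: b = 7.341 mL, y = 0.5794

subset(phantom$rc_table, label == "26.5 mL")[, c("iteration", "rc", "snr")]
#>  iteration        rc      snr
#>          0 0.6445677 12.04007
#>          1 0.5311118 17.77862
#>          2 0.6802918 15.27229
#>          3 0.7359577 13.56481
#>          4 0.7629234 12.42431
#>          5 0.7780316 11.59650
#>          6 0.7874592 10.95878
```

Row 0 is the uncorrected image. The signature of the uniform-constant
initialization is visible at iteration 1 (the image is re-blurred, so RC
*drops* to 0.53 before climbing past the uncorrected 0.64), and the
largest sphere's SNR falls monotonically as deconvolution amplifies noise —
the trade-off that motivates stopping at 4 iterations.

```r
# cohort half: simulate patients, estimate doses under all three arms
study <- run_cohort_study(cohort_study_config(
  cohort = cohort_spec(n_patients = 2),
  rc_curve = phantom$rc_curve, seed = 42))

head(study$report[, c("patient_id", "volume_ml", "tbr",
                      "ad_or", "ad_lrd", "ad_rc", "pct_lrd", "pct_rc")])
#>  patient_id volume_ml   tbr ad_or ad_lrd ad_rc pct_lrd pct_rc
#>           1     17.25 12.87  0.25   0.32  0.40   27.96  60.95
#>           2     12.72  5.47  0.14   0.18  0.24   27.63  72.73
#>           2     17.69  6.36  0.21   0.27  0.34   28.80  60.06
#>           2     29.20  3.92  0.17   0.20  0.24   20.59  44.94
study$summary
#>      arm n mean_pct    sd_pct
#> 1 OR+LRD 4 26.24611  3.804715
#> 2  OR+RC 4 59.67081 11.392598
```

Per lesion: segmented volume (mL), measured tumor-to-background ratio, mean
absorbed dose per unit injected activity (Gy/GBq) under each arm, and
percent differences against OR. Deconvolution raises every lesion's dose
(here by ~21–29%), and the recovery-coefficient correction raises it
further for small lesions, where 1/f_RC(V) is large.

Volumes can be exchanged with other tools as NIfTI or MetaImage
(`read_volume` / `write_volume`, spacing in the header, units in a JSON
sidecar), and published voxel S-value kernels can replace the default via
`read_dose_kernel`.

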