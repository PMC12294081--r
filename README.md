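# rbmdosim

Image-based red bone marrow (RBM) dosimetry for ¹⁷⁷Lu-PSMA radioligand
therapy of metastatic castration-resistant prostate cancer.

Hematologic toxicity is the main safety concern of ¹⁷⁷Lu-PSMA therapy:
the red bone marrow receives dose both from its own low uptake and from
adjacent high-uptake bone metastases. Quantifying marrow activity on
post-therapy SPECT is hard because the system blur spills lesion
activity into the surrounding marrow. `rbmdosim` implements, and lets you
stress-test on synthetic voxel phantoms, the full automated workflow for
this problem:

* **Virtual-patient phantoms** — parametric skeletons with kidneys and
  spherical bone lesions at the clinically observed
  lesion : kidney : background concentration ratio of 40 : 20 : 1,
  lesions ≥ 1 mL each and > 10 mL total, plus a simplified imaging model
  (isotropic Gaussian system blur, default FWHM 8.3 mm, and Poisson
  counting noise scaled by the time per projection).
* **Assumed marrow VOIs** — skeletal sites are classified into
  method 1 (containing lesions), method 2 (lesion-free, surface distance
  ≤ 30 mm from a lesion) and method 3 (distant). The assumed RBM VOI is
  the eroded bone compartment minus the dilated lesion mask.
* **Spill-over reduction** — matched-filter PSF estimation
  (RMSE minimization over σ = 0.1–5.0 mm), iterative Yang with
  anatomical masks (5 iterations) and Lucy–Richardson deconvolution
  (10 iterations), with RC/CNR iteration-selection sweeps on a
  six-sphere quality-control phantom.
* **Recovery-coefficient studies** — RC = A_recon / A_reference × 100%
  per VOI, per-phantom medians, cohort medians/ranges and the count of
  phantoms within the 90–110% band, swept over acquisition regimes,
  corrections and VOI volume thresholds (1/5/15 mL).
* **Dosimetry** — mono-exponential time-activity curve fits with an
  R² > 0.95 inclusion gate, time-integrated activity A₀/λ, marrow masses
  from f_rbm = f_s · f_m · c at 1.03 g/mL, MIRD-style mass-scaled
  S-values, mass-weighted patient self dose, kidney + remainder-of-body
  cross dose, first-order uncertainty propagation, and Spearman
  correlation of cumulative dose with blood-count changes.

## Worked example

```r
library(rbmdosim)

spec <- sample_phantom_spec(seed = 7)      # one virtual patient
ph   <- build_phantom(spec)
ph$labels
#> <site_label_map> 11 skeletal sites, 2 kidney labels, 134 lesion voxels

table(classify_sites(ph$labels, ph$labels$lesion_mask))
#> 1 2 3
#> 3 3 5

rec <- run_rc_experiment(list(spec), corrections = c("none", "IY_gt"))
aggregate(rc_percent ~ method + correction, rec, median)
#>   method correction rc_percent
#> 1      1      IY_gt  102.49785
#> 2      2      IY_gt   98.73016
#> 3      3      IY_gt  101.72840
#> 4      1       none  169.18415
#> 5      2       none   98.73016
#> 6      3       none  101.72840
```

Three of the eleven skeletal sites carry lesions (method 1); without
correction their median recovery coefficient is 169% — the spill-over
inflation the study design is about — while lesion-free sites (methods
2/3) recover within a few percent of 100%. Iterative Yang with
ground-truth masks brings the method-1 median back to ~102%.

```r
estimate_psf(ph$reference, gaussian_blur(ph$reference, 3.5))
#> <psf_estimate> sigma = 3.50 mm, FWHM = 8.24 mm (RMSE 0)

fit_monoexp(c(24, 48, 72), c(21.3, 14.9, 10.5))
#> <tac_fit> A0 = 30.35 MBq, lambda = 0.01477 /h (T1/2 = 46.9 h), R^2 = 1.0000 [included]
```

The TAC fit extrapolates to an injection-time activity of 30.4 MBq with
an effective half-life of 46.9 h; its time-integrated activity
(`tia_monoexp`) feeds the S-value dose calculation
(`self_dose`, `cross_dose`, `dose_report`).

The pipeline can also be driven end to end (`run_pipeline()`, or
`Rscript inst/cli/rbmdosim.R --config run.yaml`): every run writes a
manifest of artifact checksums, and identical config + seed reproduces
identical checksums.

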