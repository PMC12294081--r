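---
title: "Methods: synthetic phantoms, spill-over reduction, and red-bone-marrow dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic phantoms, spill-over reduction, and red-bone-marrow dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rbmdosim` estimates the absorbed dose to the red bone marrow (RBM) in
¹⁷⁷Lu-PSMA radioligand therapy from quantitative activity images, and
provides a synthetic virtual-patient framework to characterize the
accuracy of that estimation. This vignette is the package's account of
the science: the models, their assumptions, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not
demonstrate.

## The quantification problem

RBM is distributed on the sub-millimetre scale and cannot be resolved by
clinical SPECT. Its uptake is therefore inferred from macroscopic
skeletal-site VOIs, under the assumption that all activity in a
lesion-free bone compartment belongs to the marrow. Two error sources
dominate: system blur spills activity out of low-uptake marrow and, much
more severely, spills activity *in* from adjacent high-uptake bone
metastases; and counting noise adds variance that scales inversely with
the acquisition time per projection.

## Virtual-patient phantoms and the imaging model

`sample_phantom_spec()` draws a simplified skeleton — five stacked
vertebra-like boxes, a pelvis-like box, two femur-like boxes, two
distant humerus-like boxes, a sternum-like box — plus two ellipsoidal
kidneys, on a 64³ grid at 4.8 mm isotropic spacing (consistent with a
128 × 128 clinical matrix at half resolution; fixtures use smaller grids
purely for speed, and all problem sizes below are the package's own
desk-scale choices). Spherical lesions (2–5 per phantom, radius 7–14 mm)
are placed fully inside randomly chosen vertebra/pelvis/femur sites.
The constraints of the cohort design are enforced on the *voxelized*
geometry: every lesion ≥ 1 mL, lesions non-overlapping, and total lesion
volume > 10 mL, redrawing otherwise. This mirrors a cohort inclusion
filter rather than tuning: phantoms below the threshold are simply not
part of the study population.

Activity is piecewise constant at the lesion : kidney : background ratio
of 40 : 20 : 1 (the mean ratio reported for ¹⁷⁷Lu-PSMA patients), with a
background of 25 kBq/mL so that marrow VOIs sit at the "few tens of
kBq/mL" level typical post-therapy. Lesion-free bone defaults to the
background level and is configurable (`marrow_concentration_kBq_mL`),
since only the three-way ratio is empirically constrained.

The imaging chain — Monte Carlo projection simulation plus iterative
reconstruction with resolution modelling in the real study — is modelled
end-to-end as a single isotropic Gaussian blur followed by voxelwise
Poisson counting. This is justified by the fact that the residual blur
of such a chain is itself well described by one Gaussian PSF; the
default σ = 3.525 mm corresponds to the 8.3 mm FWHM found by matched
filtering. Counting noise uses expected counts =
concentration × calibration × time-per-projection, with calibration
0.01 counts/(kBq/mL·s) per voxel chosen so that the default 5 s regime
produces clearly visible noise at marrow concentrations while 15 s
reduces the relative standard deviation by √3. Two deliberate
departures from reality are documented rather than modelled: noise is
applied in image space (not in projections), and reconstruction
artifacts other than blur are absent. The practical consequence is that
deconvolution is *better* posed here than clinically — see "Limitations".

## Assumed marrow VOIs and site classification

Sites are classified by the ground-truth lesion geometry: method 1
contains lesion voxels; method 2 is lesion-free with a lesion within
30 mm surface-to-surface distance; method 3 is distant. Surface
distance is the minimum Euclidean distance between surface-voxel
centers (a surface voxel has a face-adjacent outside neighbor);
overlapping masks have distance 0. Center-to-center semantics make the
two-single-voxel case exact (3 voxels apart at 4.8 mm spacing = 14.4 mm)
and leave the 30 mm classification unaffected.

The assumed RBM VOI is `erode(site) \ dilate(lesions)`: one erosion
pass excludes the cortical margin, one dilation pass guards against
lesion spill-over. The structuring element is the 6-connected cross
(the default of common array-morphology libraries; 26-connectivity is
available), with one iteration each. Lesion connected components use
26-connectivity, since blurred lesions are blob-like and diagonal joins
are expected. VOIs below the volume threshold (1 mL default; 1/5/15 mL
in the sweeps) are excluded.

Lesion segmentation on images mimics the automated clinical rule: an
SUV ≥ 2 prefilter inside bone compartments, then Otsu thresholding of
the surviving values, then removal of components < 1 mL. SUV uses body
weight; Otsu uses a 256-bin histogram spanning the sample range with
ties broken toward the lower bin edge.

## Spill-over reduction

The PSF is estimated by matched filtering: blur the reference
distribution with σ = 0.1–5.0 mm in 0.1 mm steps, compute whole-grid
RMSE against the reconstruction, take the argmin (FWHM = 2√(2 ln 2)·σ).
RMSE is unweighted and unmasked; the estimate is exact for on-grid σ in
the noise-free case and within one grid step off-grid.

Two corrections are implemented from their canonical published schemes:

* **Lucy–Richardson** (`richardson_lucy()`): multiplicative updates
  `e ← e · blur(img / blur(e))`, non-negativity preserved, 10 iterations
  by default.
* **Iterative Yang** (`iterative_yang()`): per iteration, a
  piecewise-constant prior from the current regional means (supplied
  masks plus the background complement), update `prior · img/blur(prior)`,
  5 iterations by default. Masks are either ground truth (phantom
  labels) or Otsu-derived from the reconstruction — the clinical
  situation. For the Otsu kidney masks, the threshold is applied within
  the dilated kidney neighborhood.

All convolutions use reflective padding, which conserves flux near
borders better than zero padding (a deviation of unknown direction from
any particular clinical implementation). The iteration defaults are the
operating points selected by `select_iterations()` sweeps; since no
standard definition of CNR exists in this context, the package defines
CNR = (sphere mean − background mean)/background SD with the background
sampled ≥ 15 mm from any sphere, and selects the smallest iteration
count whose mean sphere RC is within 5% of its plateau (the value at
the largest grid entry) while CNR stays ≥ 80% of its maximum; with an
exactly constant background the CNR is undefined and the selection
falls back to RC alone.

## Recovery-coefficient study

RC = A_recon/A_reference × 100% per VOI; per phantom the median over its
VOIs; per cohort the median, min–max range and IQR of the per-phantom
medians (the range statistic is deliberately emitted in all three forms)
plus the count of phantoms inside the 90–110% band. Medians use the
midpoint convention for even counts. The default cohort is 30 seeded
phantoms — a desk-scale stand-in for a much larger clinical-PET-derived
population, so band *counts* are comparable only as trends, never as
values. Kidney and lesion RC rows are available (`include_organs`) with
ground-truth masks.

Observed behaviour on the shipped conditions: method-1 medians without
correction sit far above 110%; iterative Yang with ground-truth masks
returns them closest to 100%, Otsu-masked IY gives intermediate
improvement; methods 2/3 stay near 100% with ≥ 60% of phantoms in the
band; raising the volume threshold from 1 to 15 mL lowers the method-1
median. One caveat is intrinsic to the simplified imaging model:
because the blur is exactly Gaussian and noise is moderate,
Lucy–Richardson deconvolution performs unrealistically well and tends to
slightly *over*-correct (medians just below 100%). The package
therefore ranks corrections by residual quantification error
(|median − 100%|), under which the anatomically constrained IY with
exact masks remains the most effective — matching the qualitative
ranking expected against real reconstructions, where LR is weakest.

## Dosimetry

Site TACs (total VOI activity at 24/48/72 h) are fitted as
A(t) = A₀·e^(−λt) by Levenberg–Marquardt least squares on the activity
scale, started from the log-linear fit. Fits enter dosimetry only if
R² > 0.95 and λ > 0. The TIA is A₀/λ (integration 0→∞ from injection;
no rise phase is modelled, the first scan being at 24 h), with
delta-method uncertainty from the (A₀, λ) covariance; an exact
(zero-residual) fit has zero covariance by convention.

Marrow masses use f_rbm = f_s·f_m·c and density 1.03 g/mL. The shipped
composition table maps site names to three generic classes
(vertebra-like: 0.75/0.75/0.70; pelvis-like: 0.60/0.70/0.48;
long-bone-like: 0.25/0.75/0.25) — reference-human, literature-informed
values that are fully overridable, since patient-specific composition
(MRI/DEQCT) is out of scope.

Self dose treats each site's marrow as its own self-dose compartment:
dose_site = TIA · S_self · (m_ref/m_site), the inverse-mass scaling
appropriate for the short-range beta component; the patient value is
the mass-weighted mean over included sites, per GBq injected. Cross
dose assumes kidney + remainder-of-body sources: the remainder TIA is
total-body TIA (mono-exponential fit of the whole-image activity) minus
kidney and marrow TIAs, lesions being implicitly part of the remainder;
photon-dominated cross S-values scale as (m_ref_TB/m_TB)^(2/3), and the
remainder S-value derives from the total-body one via the MIRD
uniform-source identity
S(rbm←rem) = [m_TB·S(rbm←TB) − m_kid·S(rbm←kid) − m_rbm·S(rbm←rbm)]/m_rem.
The shipped S-values are **synthetic placeholders**, physically
motivated for ¹⁷⁷Lu (self term from the mean beta energy per decay at a
1170 g reference marrow; total-body term consistent with the identity
above so the remainder term is positive) and exist so the machinery is
fully exercisable; clinical use requires supplying measured phantom
S-values via `read_svalue_table()`. Both scaling exponents live in the
config for the same reason.

Uncertainties propagate first order: through TIA = A₀/λ, through the
per-site mass scaling, and through the mass-weighted mean (mass enters
both the weights and the scaling; the weight sensitivity is kept first
order). Against a 10⁵-sample Monte Carlo resample of (A₀, λ) the
delta-method site uncertainty agrees within 10% in the small-noise
regime (CV ≤ 10%); at larger noise the 1/λ nonlinearity skews the Monte
Carlo distribution and first-order propagation underestimates.

Cumulative dose per patient-cycle is the running sum of total dose ×
injected activity; blood analytes are compared as change from the
pre-treatment baseline, and associations use Spearman's rank
correlation with midranks for ties, flagged (not errored) for constant
inputs.

## Determinism and numerical choices

Every stochastic step takes an explicit seed; a single pipeline seed
fans out to per-stage child seeds through a deterministic integer
recurrence keyed by stage name, so stages can be rerun in isolation.
RNG state is saved and restored around every draw. Pipeline NIfTI
outputs are written uncompressed because gzip headers embed a
timestamp, which would defeat checksum-level reproducibility; the
manifest hash covers the scientific configuration, not the output
directory. Tiny negative values from convolution round-off are clipped
at −10⁻¹²; Richardson–Lucy guards divisions with a 10⁻¹² floor.

## What the synthetic experiments show — and what they don't

Passing the shipped experiments demonstrates that the workflow's logic
is correct and self-consistent: VOI construction, classification,
RC accounting, TAC/TIA algebra, mass weighting and error propagation
all recover analytically known ground truths, and the spill-over
phenomenology (method-1 inflation, its reduction by anatomical PVC, the
volume-threshold effect, the noise–time trade-off) reproduces the
expected trends. They do **not** demonstrate clinical accuracy: the
phantom geometry is parametric rather than patient-derived, the imaging
model omits scatter, attenuation residuals, reconstruction
non-stationarity and projection-domain noise, lesion uptake is uniform,
the S-values are placeholders, and cohort band counts are therefore
trend-level statements only. The 175-phantom clinical-PET-derived
cohort and the 20-patient dose statistics of the motivating application
are outside what a synthetic study can reproduce.
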