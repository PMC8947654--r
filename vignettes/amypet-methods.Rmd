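---
title: "Quantifying amyloid PET with an MRI-driven SUVR pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid PET with an MRI-driven SUVR pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amypet)
```

## The problem

Amyloid PET scans are read clinically as positive or negative for cortical
amyloid-beta deposition. Quantification supports that read with a number: the
standardized uptake value ratio (SUVR), the mean tracer uptake in cortical
target regions divided by the mean in a reference region with stable,
non-specific uptake — here the pons. Computing SUVR from a raw scan pair
requires a chain of image-processing steps, and the chain, not the formula,
is where quantification pipelines differ: how the anatomy is parcellated, how
PET and MRI are brought into register, and whether the limited scanner
resolution (the partial volume effect) is corrected before averaging.

`amypet` implements that chain end to end:

1. **Conformation** — the T1 MRI and its parcellation label map are
   re-oriented to right-anterior-superior (RAS) axes and resampled to a
   1 mm isotropic working grid.
2. **Co-registration** — the PET volume is rigidly registered to the MRI by
   maximising Mattes-style mutual information, then resampled onto the
   working grid.
3. **Partial-volume correction** — regional means are corrected with the
   geometric transfer matrix (GTM) method under an isotropic Gaussian
   point-spread function (PSF).
4. **Quantification** — parcel means are merged into five composites
   (frontal, anterior/posterior cingulate, lateral parietal, lateral
   temporal, striatum) by the volume-weighted mean, divided by the pons
   mean, and the global SUVR is thresholded (strictly greater than 0.61 is
   positive).

The anatomical segmenter itself is out of scope: the pipeline takes any
integer label map in MRI space, plus a TSV *region scheme* mapping labels to
composites and naming the reference parcel. An illustrative 97-parcel scheme
ships with the package (`default_scheme()`); it is synthetic — real
deployments supply the scheme matching their segmenter.

## The SUVR model

For a composite with member parcels $n = 1 \dots N$, mean intensities
$\mathrm{MEAN}(I_n)$ and volumes $V_n$,

$$
\mathrm{SUVR} \;=\;
\frac{\sum_n \mathrm{MEAN}(I_n)\, V_n \;/\; \sum_n V_n}
     {\mathrm{MEAN}(I_\mathrm{pons})} .
$$

The global SUVR applies the same formula over the union of all composite
members, which makes it algebraically the volume-weighted mean of the
composite SUVRs — a property the test suite asserts to 1e-12, together with
invariance under any common rescaling of the intensities. Equality with the
cutoff is classified negative: the published rule speaks only of "higher
than" and "lower than" 0.61, so the boundary case had to be decided; strict
inequality is the conservative choice for a positivity call.

## Registration

Registration is 6-parameter rigid (Euler x,y,z rotations about the fixed
image's centre of mass, then translation), maximising the mutual information
of the joint intensity histogram (32 bins per image, linear partial-volume
bin weighting, all voxels contributing — no stochastic sampling, so results
are exactly reproducible). The optimizer is steepest ascent on a central
finite-difference MI gradient; each step length comes from bracketing (step
doubling until the metric falls) followed by golden-section line search to
1e-3 of the bracket. Rotations are scaled by ~57 mm/radian so one degree and
one millimetre are comparable steps. A 3-level multiresolution pyramid
(factors 4, 2, 1) widens the capture range; initialisation aligns intensity
centres of mass. Non-convergence within the iteration budget is reported as
a flag on the result, never an exception, and the per-iteration metric log
is returned for audit.

The PET is always the moving image: the parcellation lives in MRI space, so
quantification happens on the MRI working grid and only the PET is ever
interpolated (trilinearly, zero-filled outside its field of view).

One behaviour worth knowing: on *noise-free piecewise-constant* images the
MI optimum can sit a fraction of a voxel away from the true alignment,
because sub-voxel interpolation enriches the joint-histogram alphabet while
keeping the intensity mapping almost deterministic. With realistic noise the
optimum returns to the true alignment; the registration tests therefore use
noisy phantoms, and the degenerate case is tested with the registration
stage disabled.

## Partial-volume correction

Scanner resolution is modelled as an isotropic Gaussian PSF parameterised by
its full width at half maximum (FWHM, mm; default 2 mm, the value used with
the scheme this package follows; $\sigma = \mathrm{FWHM} / 2\sqrt{2\ln 2}$).
The GTM entry $\omega_{ij}$ is the mean over region $i$'s voxels of the
PSF-smoothed binary indicator of region $j$ — the fraction of region $i$'s
observed signal originating in region $j$. Corrected means solve
$\omega c = \mathrm{observed}$ by QR least squares, without a non-negativity
constraint. Correction runs at the full parcel level; composite merging
happens afterwards, and the pons reference is taken from the corrected means
when PVC is on (`pipeline_config(reference_from = "observed")` overrides).

Design points that needed deciding:

* **Background as a region.** Label 0 (air/scalp) is included as an explicit
  GTM region by default so cortical spill-out is modelled rather than lost.
* **Boundary handling.** Smoothing is zero-padded: blur mass that leaves the
  grid is gone. Rows of $\omega$ for regions at least $4\sigma$ from every
  grid face sum to 1 (asserted to 1e-6 in tests); face-adjacent regions have
  deficient row sums, which is the physically correct statement that part of
  their signal left the field of view.
* **Modelling the full measurement chain.** When the PET arrives on its own
  scanner grid (e.g. 1.3364 x 1.3364 x 3 mm), the pipeline resamples it to
  the 1 mm working grid, and that interpolation — plus the coarse-grid
  sampling it implies — is extra smoothing the plain PSF model does not see.
  By default the pipeline therefore pushes each region indicator through the
  same round trip (working grid to PET grid and back, under the estimated
  transform) after PSF smoothing, so the GTM inverts the measurement chain
  that actually produced the quantified image. On the synthetic subjects this
  reduces the global SUVR bias from about +0.018 to under 0.004. Disable
  with `pipeline_config(gtm_model_resampling = FALSE)` to get the textbook
  PSF-only GTM, which `build_gtm()` itself always computes.
* **Conditioning.** The condition number of $\omega$ is recorded; above 1e4
  the correction warns (tiny parcels relative to the PSF are the usual
  cause, and merging them is the usual cure).

## The synthetic subjects

`generate_subject()` builds a fully known test subject: an ellipsoidal brain
(deliberately wider front-to-back than left-to-right, so no rotation leaves
the anatomy invariant), ten cortical sector parcels — two per composite,
each with a slightly different T1 level, giving registration azimuthal
structure — a deep white-matter core, and a pons sphere. PET activity is
piecewise-constant per-parcel uptake expressed as multiples of the pons
value, blurred with the PSF, degraded with additive Gaussian noise, and
sampled onto an anisotropic PET grid (1.3364 x 1.3364 x 3 mm, field of view
padded 16 mm beyond the MRI box, as scanner FOVs extend beyond the head)
under a known rigid misalignment — default 5 degrees about z and
(3, -2, 1) mm, the magnitude the registration acceptance check probes.

Default conditions: negative subjects sit at a true global SUVR of 0.50 and
positive ones at 0.82 (typical pons-referenced levels for the two groups,
with the regional profile scaled so the global value is hit exactly);
PET noise SD is 2% of the pons activity; PSF FWHM is 2 mm. The cohort
generator mirrors the cross-method comparison setting: per-subject latent
SUVR from N(0.50, 0.04) or N(0.82, 0.15), observed through three
pseudo-methods with fixed offsets (0, -0.04, +0.02) — the biases reported
between MRI-based quantification tools — plus N(0, 0.015) measurement noise,
chosen so the implied limits of agreement match the published scale.

What the phantom does *not* emulate: real anatomy (no template brains, no
cortical folding), Poisson counting noise, scatter and attenuation
artefacts, motion, or segmentation errors. Passing the phantom checks
therefore demonstrates that the *computational* chain is correct and
self-consistent — not that the pipeline is robust to the failure modes of
clinical data.

## Agreement statistics

The evaluation battery compares quantification methods the way method-
comparison studies do:

* **Welch t-tests** (raw samples or published mean/SD/n summaries) for
  group separation.
* **Two-way single-measure ICC** in both the absolute-agreement and
  consistency forms, computed from the two-way ANOVA mean squares with
  F-based 95% bounds (Satterthwaite degrees of freedom for the absolute
  form). Negative lower bounds on small samples are a known property of this
  construction, not an error. The consistency form is at least the absolute
  form whenever real subject variance and systematic rater offsets are
  present (MSR, MSC >= MSE); the untruncated estimators can invert that
  ordering on pure noise, and the package keeps the untruncated standard
  forms.
* **Bland-Altman** mean difference with mean +/- 1.96 SD limits of
  agreement, with `autoplot()` for the conventional plot.
* **Classification metrics** at the single 0.61 operating point: accuracy,
  sensitivity, specificity, and the two-point ROC area
  (sensitivity + specificity)/2 — the only AUC definition available when a
  method is observed as thresholded labels. `reconstruct_confusion()`
  inverts printed (rounded) metric triples back to the unique integer
  confusion matrix, which is how the package's acceptance script re-derives
  a published classification row from first principles.

## Numerical choices and limitations

* Trilinear interpolation everywhere for intensities, nearest-neighbour for
  labels (labels are never averaged, and resampling can never invent a
  label). Resampling coordinates within 1e-9 voxel of the lattice are
  snapped, so grid-coincident resampling is exact.
* Conformation of an already-conformed volume returns it unchanged
  (idempotence), and out-of-grid samples are zero (air).
* The Gaussian kernel is the discretized Gaussian truncated at $4\sigma$ and
  renormalised; GTM and phantom use the same definition, and the test-suite
  oracle re-derives it by direct 3-D convolution.
* Problem sizes: the full-scale checks (registration recovery, GTM
  inversion, end-to-end recovery) run on 96 mm-cube subjects; module tests
  use 32-64 mm cubes. At 96 cubed, registration takes tens of seconds and
  the whole pipeline a few minutes on one core.
* Eq.-level arithmetic (composite merging, scale invariance) is exact to
  1e-12; image-mediated quantities carry interpolation-level error, and the
  end-to-end recovery budget on the default phantom is 0.02 SUVR.
* The pipeline is deterministic given its inputs and configuration; the
  only randomness in the package lives in the generators, which take
  explicit seeds.
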