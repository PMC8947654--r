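# amypet

Amyloid PET SUVR quantification with MRI-based parcellation, in R.

Amyloid PET is read as positive or negative for cortical amyloid-beta
deposition; quantification backs that read with the standardized uptake
value ratio (SUVR) — mean tracer uptake in cortical target regions divided
by the mean in the pons, a reference region with stable non-specific uptake.
`amypet` implements the full processing chain from a raw T1 MRI / static PET
pair and a brain parcellation to a classified SUVR report, plus the
statistical battery used to compare quantification tools, and a seeded
digital-phantom generator so every stage can be validated against known
ground truth without clinical data.

The pipeline has four stages:

1. **Conformation** — MRI and label map resampled to a 1 mm isotropic,
   RAS-oriented working grid.
2. **Rigid co-registration** — PET registered to MRI by maximising Mattes-
   style mutual information (gradient ascent with golden-section line
   search, multiresolution pyramid), then resampled onto the working grid.
3. **Partial-volume correction** — geometric transfer matrix (GTM): with a
   Gaussian point-spread function of FWHM 2 mm, `omega[i, j]` is the
   fraction of region *i*'s observed signal originating in region *j*, and
   corrected regional means solve `omega %*% c = observed`.
4. **Quantification** — volume-weighted SUVR per composite region and
   globally,

   `SUVR = (sum_n MEAN(I_n) * V_n / sum_n V_n) / MEAN(I_pons)`,

   with global SUVR > 0.61 classified amyloid-positive.

Parcellation is data, not code: any integer NIfTI label map plus a TSV
scheme (label id, parcel name, composite, reference flag) works. An
illustrative synthetic 97-parcel scheme ships as `default_scheme()`.

## Worked example

Generate a synthetic amyloid-negative subject (true global SUVR 0.50, PSF
2 mm, 2% noise, PET misaligned by 5 degrees / (3, -2, 1) mm on an
anisotropic scanner grid) and push it through the full pipeline:

```r
library(amypet)

s <- generate_subject(phantom_spec(grid_size = c(64, 64, 64), seed = 7))
res <- run_pipeline(s$mri, s$pet, s$labels, s$scheme)
res$report
#> <suvr_report> global SUVR 0.5003 (negative at cutoff 0.61), PVC applied, reference mean 99.98
#> # A tibble: 5 x 4
#>   composite                     suvr volume_mm3 n_parcels
#>   <chr>                        <dbl>      <dbl>     <int>
#> 1 frontal                      0.485      11026         2
#> 2 anterior/posterior cingulate 0.519      12872         2
#> 3 lateral parietal             0.500       9928         2
#> 4 lateral temporal             0.468      12990         2
#> 5 striatum                     0.532      11066         2
```

The estimated global SUVR (0.5003) recovers the constructed truth (0.5000)
through misalignment, blur and noise, and the subject is correctly
classified negative at the 0.61 cutoff. `res$record` is the per-stage run
record; `res$transform` the recovered rigid transform; `tidy(res$report)`
and `glance(res$report)` give flat tibbles; `autoplot(res$report)` plots
the composite profile.

Cross-method agreement on a synthetic cohort (135 negative / 83 positive
subjects, three pseudo-methods with between-method offsets 0, -0.04, +0.02):

```r
tb <- generate_cohort(n_neg = 135, n_pos = 83, seed = 7)
agr <- run_agreement(tb)
dplyr::filter(agr$bland_altman, region == "global")
#> # A tibble: 3 x 8
#>   method_a  method_b  region mean_diff sd_diff loa_lower loa_upper     n
#> 1 proposed  petsurfer global    0.0400  0.0212  -0.00149    0.0815   218
#> 2 proposed  pmod      global   -0.0190  0.0210  -0.0602     0.0221   218
#> 3 petsurfer pmod      global   -0.0590  0.0221  -0.102     -0.0157   218
```

The constructed 0.04 / -0.02 biases surface as the Bland-Altman mean
differences; `agr$icc` holds the paired intraclass correlations (absolute
and consistency forms with 95% bounds), `agr$ttests` the group t-tests and
`agr$classification` per-method confusion counts with accuracy,
sensitivity, specificity and two-point AUC.

A thin command-line front end with `quantify`, `register`, `pvc`, `agree`
and `phantom` subcommands is installed at
`system.file("cli", "amypet.R", package = "amypet")`.

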