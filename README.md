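# gasf — structure–function analysis of geographic atrophy

`gasf` quantifies geographic atrophy (GA), the atrophic late stage of
age-related macular degeneration, from per-feature OCT segmentation
probability volumes, and relates lesion topography to visual function. It
is written for researchers in retinal imaging who have per-A-scan (or
per-b-scan pixel) probabilities for the three constituent GA features —
RPE-loss, photoreceptor degeneration (PDR) and choroidal hypertransmission
— plus a foveal annotation and visual-acuity outcomes, and who want a
reproducible path from those volumes to spatially resolved predictive
importance.

## What it computes

- **En-face maps.** Each A-scan is reduced to a presence probability
  (column maximum); RORA (RPE and outer retinal atrophy) is derived as the
  per-A-scan co-occurrence of the three features, implemented as the
  cell-wise minimum `RORA(x) = min(RPE(x), PDR(x), HT(x))` so that
  thresholding commutes with the binary AND at every threshold. Lesion
  areas are thresholded cell counts in mm².
- **Fovea-centred ETDRS grids.** Maps are resampled bilinearly onto a grid
  with the fovea on the centre cell; left eyes are mirrored so +x is nasal
  for every eye. Cells are labelled by the nine ETDRS subfields (central
  1 mm disc, parafoveal ring to 3 mm, perifoveal ring to 6 mm, quadrants
  split at the 45° diagonals).
- **Bootstrapped random-forest regression.** With one predictor per
  (feature, grid cell), visual acuity under standard (VA) or low
  luminance (LLVA), or the low-luminance deficit (LLD = VA − LLVA), is
  predicted by random-forest regression evaluated over replicates that
  bootstrap-resample *patients* and split 80/20 at the patient level
  (both eyes of a patient stay on one side). Reported per model:
  r² (coefficient of determination on held-out eyes, median across
  replicates) and MAE in ETDRS letters with quartiles.
- **Importance maps.** Impurity (variance-reduction) importances are
  averaged across replicates, renormalised to percentages summing to 100,
  mapped back to grid cells, summed per ETDRS region × feature, and
  rendered as en-face heatmaps; foveal vs non-foveal shares complement to
  100 exactly.
- **Synthetic cohorts.** `simulate_ga_cohort()` generates correlated
  lesion volumes (nested features, patient-level burden, ~15%
  foveal-sparing eyes, cohort median areas near clinically typical
  values) and outcomes under a configurable linear structure–function law
  — the test bed for the whole pipeline.

## Worked example

```r
library(gasf)

cohort <- simulate_ga_cohort(synth_config(n_patients = 60, rng_seed = 7))
cohort
#> <ga_cohort> 87 eyes / 60 patients, 49 x 49 raster over 6 mm
#>   median VA 59.7, LLVA 38.6, LLD 20.5 letters

round(cohort_median_areas(cohort), 2)
#> RPE_LOSS      PDR       HT     RORA
#>     8.95    14.48    10.41     7.98

tab <- build_feature_table(cohort, outcome = "va", downsample_k = 7)
fit <- fit_structfunc(tab, n_replicates = 25, seed = 7)
fit
#> <structfunc_fit> outcome = va, 25 bootstrap replicates
#>   r2 0.27  MAE 10.0 (8.9-12.2) ETDRS letters

ri <- aggregate_by_region(fit, etdrs_labels(7, 3))
ri
#> Importance (% contribution) by ETDRS region and feature:
#>                RPE_LOSS  PDR   HT RORA  Sum
#> foveal              9.0  2.3 18.2 23.6 53.1
#> inner_superior      0.6  1.2  1.2  0.8  3.8
#> ...
#> Sum                15.6 13.1 32.4 31.8 92.9
#> Outside 6 mm circle: 7.1%

foveal_shares(ri)$foveal_share
#> [1] 53.08097
```

The cohort medians are the thresholded lesion areas (mm²) at the default
0.5 probability threshold — note the nesting PDR > HT > RPE-loss > RORA.
The fit line reads: across 25 patient-level bootstrap replicates, voxel
probabilities explain about 27% of VA variance with a typical error of 10
ETDRS letters (two lines on the chart). The region table attributes over
half of the model's predictive contribution to the central foveal
subfield, dominated by RORA — as expected, since the simulated VA law acts
through foveal RORA. `plot(fit)` draws the per-feature en-face heatmaps.

An end-to-end run with one call, and a command-line driver:

```r
report <- run_pipeline(pipeline_config(seed = 1), report_path = "report.json")
```

```sh
Rscript inst/cli/gasf.R run --out results --seed 1
Rscript inst/cli/gasf.R simulate --out cohort_dir --seed 1
```

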