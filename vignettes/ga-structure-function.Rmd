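---
title: "Structure-function analysis of geographic atrophy with gasf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-function analysis of geographic atrophy with gasf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gasf)
```

## The problem

Geographic atrophy (GA) is the atrophic late stage of age-related macular
degeneration: confluent loss of the retinal pigment epithelium (RPE) and the
overlying photoreceptors across the macula. On OCT it is characterised by
three co-localising features -- RPE-loss, photoreceptor degeneration (PDR)
and choroidal hypertransmission -- whose co-occurrence defines RPE and outer
retinal atrophy (RORA). How the *topography* of these features relates to
visual function is the scientific question this package operationalises:
given per-feature segmentation probability volumes for a cohort of eyes,
quantify lesions on a common fovea-centred grid, predict visual acuity under
standard (VA) and low luminance (LLVA), and localise which features at which
retinal locations carry the predictive signal.

The pipeline has five stages, each usable on its own:

1. **En-face reduction** (`build_enface`, `derive_rora`, `lesion_area`):
   per-A-scan presence probabilities, derived RORA, thresholded areas.
2. **Spatial standardisation** (`standardize_map`, `etdrs_labels`,
   `region_means`): fovea-centred, laterality-normalised grids and ETDRS
   subfield summaries.
3. **Feature table** (`build_feature_table`): one row per eye, one
   predictor per (feature, grid cell), optionally block-averaged.
4. **Bootstrapped random-forest regression** (`fit_structfunc`):
   patient-level 80/20 evaluation, r-squared and MAE, impurity importance.
5. **Importance mapping** (`importance_by_cell`, `aggregate_by_region`,
   `foveal_shares`, `plot`): percentage contributions per ETDRS region and
   feature, en-face heatmaps.

A synthetic-cohort simulator (`simulate_ga_cohort`) generates correlated
lesion volumes and outcomes under a known structure-function law, so every
stage is testable end to end without clinical data.

## En-face reduction and RORA

Segmentation models emit a probability per pixel of each b-scan. Clinically
the relevant question per A-scan (depth column) is *presence*, so the column
is reduced by its maximum; the binary label applies a `>=` threshold. The
mean is available as a sensitivity option, but presence detection is the
default because a feature confined to a thin band of depth pixels is still
fully present at that retinal location.

RORA is defined as retinal area where all three constituent features are
present. On probability maps we take the cell-wise **minimum**: it is the
fuzzy AND whose thresholding commutes with the binary definition --
`min(a, b, c) >= t` exactly when `a >= t & b >= t & c >= t` -- so the
derived probabilistic map is consistent with the binary co-occurrence at
*every* threshold, not just the default. This subset relation
(RORA area never exceeds any constituent's area) is enforced by construction
and re-checked as a property test.

Areas are cell counts times the per-cell area in mm^2, with no sub-cell
geometry; at the default 49 x 49 raster over 6 mm one cell is
(6/49)^2 ~ 0.015 mm^2, well below clinical reporting precision. The default
binarisation threshold is 0.5; model-specific optimised thresholds are
acquisition dependent, so the threshold is an explicit argument everywhere.

## Fovea-centred standardisation and the ETDRS grid

Eyes are comparable only after two normalisations: translation so the
annotated fovea sits on the exact centre cell (hence odd grid resolutions),
and horizontal mirroring of left (OS) eyes so that +x is nasal for every
eye. Without the mirroring, nasal/temporal importance aggregation would
average anatomically opposite locations. Resampling is bilinear, which
respects the interpolation view of voxel localisation relative to the
fovea; target cells falling outside the scanned square receive a
configurable fill (0 by default, `NA` to exclude from summaries). No
rotation or torsion correction is attempted.

The ETDRS grid partitions the 6 mm circle into a central 1 mm disc, an
inner (parafoveal) ring to 3 mm and an outer (perifoveal) ring to 6 mm,
with rings split at the 45-degree diagonals into superior, nasal, inferior
and temporal quadrants. Cells are labelled by their centre coordinates with
half-open radius bins `[0.5, 1.5)`, `[1.5, 3)` mm and half-open angle
intervals, so every cell gets exactly one label deterministically; the
published subfield definitions do not specify boundary tie rules, so any
fixed convention is acceptable and this one is documented here. The
discretised subfield areas converge to the analytic ring-quadrant values
(central disc pi/4 ~ 0.785 mm^2, printed clinically as 0.79 mm^2):

```{r etdrs}
round(etdrs_region_areas(etdrs_labels(490, 3)), 3)
```

## The regression model

The feature table holds, per eye, the standardised probability of each of
the four features at each grid cell, in a deterministic feature-major,
row-major column order. A block-mean downsampling factor `k` (default 7 on
a 49 x 49 grid, i.e. 7 x 7 blocks, 196 predictors) keeps the forest
affordable; the foveal signal concentrates on the central block either way.

Evaluation is **bootstrapped at the patient level**: each replicate
resamples patients with replacement, partitions the resampled patients
80/20, trains a random forest on the training eyes (duplicated patients
contribute duplicated rows) and scores the held-out eyes. Keeping both eyes
of a patient on one side matters because bilateral eyes share a
patient-level lesion burden; a leakage-free split is asserted by a property
test across all replicates. A plain repeated-split scheme without
resampling is available (`scheme = "split_only"`). r-squared is the
held-out coefficient of determination (test-side mean reference), MAE is in
ETDRS letters; the single reported value is the median across replicates
(mean available), with MAE quartiles. Replicates whose train outcome is
constant or whose test side has fewer than two eyes carry no defined score
and are excluded with a logged count.

Forest hyperparameters default to the conventional regression settings of
the widely used Python implementation of that era: 100 trees, all
predictors considered at every split, leaf size 5. All hyperparameters are
recorded in the result object.

Impurity (variance-reduction) importance is averaged across replicates
*first*, then renormalised to percentages summing to 100, then mapped back
to (feature, cell) and summed per ETDRS subfield. Importance on cells
outside the 6 mm circle (the corners of the square grid) is reported as an
explicit remainder rather than folded into the outer ring. Impurity
importance is known to be biased toward high-cardinality predictors; all
predictors here are probabilities on a common scale, which limits the bias,
and permutation importance can be computed from the retained per-replicate
fits if needed. The foveal share is the foveal row sum; the non-foveal
share is its complement to 100 exactly.

One published rounding quirk is worth recording: in the reference VA
importance table shipped with the package (`reference_importance("va")`),
the RPE-loss and hypertransmission column totals printed in the source
table differ from cell-wise addition by 0.1 (23.7 vs 23.6, 25.1 vs 25.2),
and in the LLVA table the printed foveal row sum is 25.5 while its cells
add to 25.6. The package reproduces the cell-wise arithmetic and keeps the
printed marginals alongside; only the self-consistent marginals are treated
as exact.

## The synthetic cohort

The simulator generates what the downstream stages consume -- per-A-scan
probability rasters -- not depth-resolved b-scan textures. Its construction:

* **Patient structure.** `n_patients` patients (default 205), each
  bilateral with probability 0.46 (about 1.46 eyes per patient); bilateral
  eyes share a log-normal patient-level burden multiplier (SD 0.35 on the
  log scale), which is what makes patient-level splitting non-trivial.
* **RPE-loss.** 1-4 lesion seeds per eye, positions drawn from an
  isotropic Gaussian centred on the fovea (SD `sparing_spread_mm`, default
  1.15 mm); the field is the maximum of radial Gaussian kernels with
  log-normal radii around `base_radius_mm` (0.86 mm), passed through a
  sharp logistic so lesions are near-binary with soft margins. Seed
  placement is fovea-biased rather than uniform because GA is a macular
  disease: uniform placement over the 6 x 6 mm field would leave roughly
  half of eyes foveal-sparing, whereas the clinical reference is about 15%.
  The spread is an exposed knob; at the default, roughly 15% of simulated
  eyes have no foveal RORA.
* **PDR.** The same kernels dilated by a per-eye halo (uniform 0.08-0.5 mm)
  plus a Poisson number of small independent patches, so PDR area
  stochastically dominates RPE-loss area.
* **Hypertransmission.** The RPE-loss field under a smooth multiplicative
  log-normal noise field (coarse 10 x 10 lattice, bilinearly upsampled;
  meanlog 0.13, sdlog 0.6), making hypertransmission slightly larger than
  RPE-loss on average while locally cutting into it.
* **RORA** is always derived via the minimum, never generated.

These shape constants were calibrated once so that the cohort median
thresholded areas approach clinically typical values (7.82 / 14.4 / 9.23
mm^2 for the three raw features, derived RORA near 6.2 mm^2) and then
frozen; the targets live in the configuration and a cohort-scale check
(within 20% at ~300 eyes, fixed seed) is part of the test suite. The
zero-area retry cap (5 draws) exists because a legal cohort can contain
near-zero lesions; after the cap the empty lesion is emitted.

**Outcomes.** The structure-function law is linear with additive Gaussian
noise, clamped to the 0-100 letter range:

* `va = intercept - b_fov * (mean foveal RORA probability) - b_area *
  (extrafoveal RORA area, mm^2) + noise`
* `lld = intercept_lld + b_pdr * (mean parafoveal PDR probability) +
  noise`, clamped to `[0, va]`; `llva = va - lld`, so `lld = va - llva`
  holds exactly on every row.

No published effect sizes exist for these coefficients, so the defaults are
calibration choices and are flagged as such: intercept 82, `b_fov` 28,
`b_area` 0.35, `lld` intercept 2, `b_pdr` 25, noise SD 12 letters. The
noise default was chosen so that the default cohort yields bootstrapped
r-squared in roughly the 0.25-0.46 band reported for clinical GA cohorts --
a calibration, not a claim of equivalence. The covariates entering the law
are computed by the same spatial machinery the analysis uses (standard
grid, ETDRS labels), so recovering them downstream is a genuine round trip
through the pipeline.

**The contrast study** (`contrast_config()`) is the package's headline
recovery experiment: VA driven *only* by foveal RORA (`b_area = 0`,
`b_fov = 20`) and LLD driven only by parafoveal PDR (`b_pdr = 55`), at
noise SD 5. The coefficients are deliberately asymmetric: LLVA inherits the
foveal RORA signal through `llva = va - lld`, so the parafoveal PDR law
must contribute comparable outcome variance for its signature to be
detectable in the LLVA model. Under this configuration the fitted VA model
places the largest row sum on the foveal region and the largest column sum
on RORA, while the LLVA model ranks PDR first -- the qualitative contrast
between standard and low-luminance acuity that motivates low-luminance
testing clinically.

## What the simulator does and does not emulate

Passing tests on synthetic cohorts demonstrate that the pipeline recovers a
known structure-function law through the full image-to-model round trip,
that the evaluation is leakage-free, and that the arithmetic of area,
aggregation and shares is correct. They do not validate segmentation-model
accuracy, real lesion morphology (no longitudinal growth, no depth texture,
radially symmetric kernels), inter-grader fovea annotation variability,
acquisition artefacts, or the clinical effect sizes themselves. Real
applications supply their own probability volumes and outcomes in the same
containers.

## Numerical choices and degenerate inputs

* Thresholding uses `>=` everywhere, so boundary probabilities count as
  present; `lesion_area` is non-increasing in the threshold.
* Bilinear resampling at exact lattice coincidence reproduces the input
  bit-for-bit (up to floating point); a 1e-9-relative tolerance guards
  exact-boundary cells against floating-point exclusion.
* Empty A-scan columns, missing fovea or laterality, geometry mismatches
  between maps, and a missing outcome column raise immediate errors naming
  the offending input.
* The master seed drives every stochastic stage through a stage-indexed
  derivation (`seed -> per-stage, per-index offsets`), all below 2^31, so
  the pipeline report is a deterministic function of configuration.
* Problem sizes used in the shipped checks: 49 x 49 rasters, ~300-eye
  cohorts, 100 bootstrap replicates, downsampling factor 7 (196
  predictors); geometry convergence is checked at 490 x 490.

## Known limitations

* Impurity importance, although matching the reference methodology, is
  biased when predictors are correlated, as neighbouring cells necessarily
  are; region sums partially absorb this but the per-cell maps should be
  read qualitatively.
* The single r-squared of a bootstrap distribution is reported as the
  median by default; reported clinical values do not state their
  aggregator, so mean aggregation is exposed as an option.
* `mtry` equal to all predictors makes trees deterministic given the
  bootstrap row sampling; ensemble variance then comes from in-forest row
  resampling only, which mirrors the reference implementation's regression
  defaults of its era.
* The standard-grid resolution for voxel-level features is a modelling
  choice (default mirrors the 49 b-scan count); published analyses do not
  state theirs.
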