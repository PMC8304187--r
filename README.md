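# petscore

Integrated tumor + bone-marrow FDG PET prognostic scoring for pancreatic
cancer, rebuilt as a fully simulation-driven, testable R pipeline.

## The problem

In pancreatic cancer, prognosis depends both on the tumor ("seed") and on
the host's systemic inflammatory state ("soil"). On staging FDG PET/CT both
are measurable:

* **Tumor factors** — total lesion glycolysis
  (TLG = MTV × mean SUV, in grams) and **first-order entropy**
  (−Σ pᵢ log₂ pᵢ of the 64-level tumor intensity histogram), a marker of
  intratumoral metabolic heterogeneity.
* **Host factor** — bone-marrow FDG uptake (**BM SUV**): the mean of
  six vertebral-body 75%-isocontour SUV means, a surrogate of the systemic
  inflammatory response.

Each tumor factor above its cutoff scores **1 point**, the host factor
above its cutoff scores **2 points**; the 0–4 total stratifies patients
into three prognostic groups (score 0–2, 3, 4) with increasingly poor
overall survival. Default cutoffs are TLG > 41.40 g, entropy > 3.40,
BM SUV > 1.53, with strict `>` comparisons.

Because no patient images or survival data are publicly available, every
stage is driven by a synthetic generator with known ground truth: digital
PET phantoms (heterogeneous tumor, six vertebrae, liver, noise) and
survival cohorts drawn from an exponential proportional-hazards model with
planted effects.

## What the package implements

| Stage | Functions |
|---|---|
| Phantom + cohort simulation | `phantom_spec()`, `generate_phantom()`, `cohort_spec()`, `generate_cohort()`, `synthetic_registry()`, `apply_eligibility_filter()` |
| Tumor segmentation | `nestle_threshold()` — adaptive threshold = 0.3 × (mean SUV of voxels > 70% of lesion max) + background mean; `default_background_mask()` |
| Marrow / liver uptake | `isocontour_mean()` (75% isocontour), `measure_bone_marrow()` (BM SUV, BLR) |
| Radiomics (41 parameters) | `discretize()` (64 relative levels), `conventional_params()` (max/peak SUV, MTV, TLG), `first_order_features()`, `build_texture_matrices()` + `higher_order_features()` (6 GLCM, 3 NGLDM, 11 GLRLM, 11 GLZLM), `extract_all()` |
| Survival statistics | `spearman_correlation()`, `maxstat_cutoff()` (maximally selected chi-square), `cox_fit()`, `harrell_c()`, `km_estimate()` |
| Scoring + stratification | `scoring_rule()`, `assign_score()`, `derive_rule()`, `evaluate_stratification()` |
| Orchestration | `run_config()`, `validate_config()`, `run_pipeline()`, CLI at `inst/cli/petscore.R` |

## Worked example

```r
library(petscore)

## a phantom with ground truth, segmented and measured
ph  <- generate_phantom(phantom_spec(seed = 42))
voi <- dilate_mask(ph$truth$tumor_mask, 2L)        # manual-VOI stand-in
seg <- nestle_threshold(ph$volume, voi, default_background_mask(ph$volume, voi))
mm  <- measure_bone_marrow(ph$volume, ph$truth$vertebra_masks, ph$truth$liver_mask)
fv  <- extract_all(ph$volume, seg$tumor_mask)
assign_score(tlg = fv[["tlg_g"]], entropy = fv[["firstorder_entropy"]],
             bm_suv = mm$bm_suv)

## a 65-patient synthetic cohort, stratified by the score
coh <- generate_cohort(cohort_spec(n = 65, seed = 42))
evaluate_stratification(coh, scoring_rule(), n_boot = 1000, seed = 42)
```

prints

```
Adaptive-threshold segmentation: threshold 2.408 SUV (0.3 x 6.349 + 0.5038), 280 tumor voxels
Bone marrow: BM SUV 1.742 over 6 vertebrae, liver 2.001, BLR 0.870
Risk score 4 (group 4): TLG 1 + entropy 1 + BM SUV 2
Prognostic stratification by the PET scoring system
    group  n events   hr ci_lower ci_upper p_value median_os
0-2   0-2 31     15 1.00       NA       NA      NA     28.38
3       3 19     13 1.91    0.903     4.03 0.09034     11.83
4       4 15     13 4.27    1.973     9.25 0.00023      5.07
C-index of the score: 0.677
```

The segmentation line shows the adaptive-threshold decomposition
(0.3 × hot-voxel mean + background mean). This phantom's tumor exceeds both
tumor cutoffs and its marrow uptake (1.742) exceeds 1.53, so it scores
1 + 1 + 2 = 4. In the cohort, hazard rises and median survival falls
monotonically across groups 0–2 → 3 → 4, and the score's concordance index
quantifies its discriminative ability.

## Command line

```sh
Rscript inst/cli/petscore.R simulate-cohort --config cohort.json --out cohort.csv
Rscript inst/cli/petscore.R features --volume vol.nii.gz --mask tumor.nii.gz --out features.csv
Rscript inst/cli/petscore.R run --config run.json
```

Exit codes: 0 success, 2 validation failure, 3 stage failure.

## Documentation

The methods vignette (`vignettes/petscore-methods.Rmd`) documents the
model assumptions, the synthetic-data design, every numerical choice
(binning, mesh surface area, tie handling, cutpoint grids) and the known
limitations of phantom-based validation.
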