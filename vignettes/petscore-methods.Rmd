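---
title: "petscore: methods, numerical choices and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{petscore: methods, numerical choices and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petscore)
```

# Overview

`petscore` implements a prognostic pipeline for pancreatic cancer staging
FDG PET/CT that integrates primary-tumor radiomics with host bone-marrow
uptake into a 0–4 score. Since no patient data are available to the
package, validation is built on a synthetic generator with known ground
truth; this vignette records the model, its assumptions, the parameters
that matter, and every place where a design decision had to be made.

# The measurement model

## Tumor segmentation

Inside a manually drawn volume of interest (VOI), the tumor is delineated
by the background-corrected adaptive threshold

$$T \;=\; 0.3 \times \bar S_{\mathrm{hot}} \;+\; \bar S_{\mathrm{bg}},$$

where $\bar S_{\mathrm{hot}}$ is the mean SUV of VOI voxels with uptake
*strictly greater* than 70 % of the VOI maximum and $\bar S_{\mathrm{bg}}$
the mean over a background region. The tumor mask keeps every VOI voxel
with SUV $\ge T$.

Decisions taken where the measurement convention is under-specified:

* **Background region.** No canonical definition exists; the package
  default (`default_background_mask()`) is a 2-voxel shell around the VOI
  with voxels above 70 % of the VOI maximum removed, and the background is
  always an *explicit argument* so any other convention can be supplied.
* **Inclusivity.** The hot-voxel set uses strict `>` (the formula speaks of
  uptake *greater than* 70 %); the final mask and all isocontours use `>=`
  so ties at the threshold are kept. The maximum voxel always qualifies,
  so the hot set is never empty; if the threshold exceeds the VOI maximum
  (a background hotter than the lesion) the error names the threshold
  rather than returning an empty tumor.
* **No connected-component filtering.** All supra-threshold VOI voxels are
  kept; margin inspection is the caller's responsibility, mirroring manual
  review practice.

## Bone-marrow and liver uptake

Per vertebra, uptake is the mean SUV inside the 75 % isocontour of its VOI
(`isocontour_mean(..., fraction = 0.75)`); BM SUV is the unweighted mean
over up to six vertebrae (fewer model the exclusion of degenerate
vertebrae), and BLR = BM SUV / liver mean. The liver reference uses the
*plain* VOI mean — the isocontour convention applies only to vertebrae,
since the liver VOI is placed in homogeneous parenchyma.

## The 41 imaging parameters

Four conventional parameters (maximum SUV; peak SUV; MTV in cm³; TLG in
g), six first-order features (histogram skewness, kurtosis, entropy,
energy; shape sphericity and compacity) and 31 higher-order texture
features (6 GLCM, 3 NGLDM, 11 GLRLM, 11 GLZLM) computed after resampling
tumor SUV into **64 relative levels** on $[0, \mathrm{SUV_{max}}]$:
$g(v) = \min(L, \lfloor \mathrm{SUV}(v)/\mathrm{SUV_{max}} \cdot L\rfloor + 1)$,
left-closed bins, top value clamped into bin $L$. Tumors under 64 voxels
are rejected — below that, texture statistics are dominated by the
discretization itself.

Numerical choices:

* **Peak SUV** has no universal definition; the package uses the mean over
  a 1 cm³ sphere (radius ≈ 6.2 mm) centred on the hottest voxel, counting
  every volume voxel whose centre falls inside (the sphere may extend
  beyond the mask).
* **Entropy is log₂** (bits), for both the first-order histogram and GLCM
  entropy.
* **Skewness/kurtosis** are the standardized third and fourth central
  moments of the discretized level distribution (kurtosis non-excess).
  They are undefined for constant or single-voxel tumors and are returned
  as `NA` — degenerate features are always flagged missing, never silently
  zeroed (the same policy yields `NA` GLCM correlation on constant
  tumors).
* **Surface area** for sphericity
  ($\pi^{1/3}(6V)^{2/3}/A$) and compacity ($A/(36\pi V^2)^{1/3}$, the
  surface relative to the equal-volume sphere — under this definition
  compacity is exactly the reciprocal of sphericity) is measured on a
  marching-tetrahedra mesh of the binary mask (six-tetrahedron Kuhn
  decomposition, midpoint vertices) followed by 60 iterations of
  shrink-free Taubin smoothing ($\lambda = 0.5$, $\mu = -0.53$).
  Voxel-face counting overestimates a ball's surface by ~50 % (sphericity
  ≈ 0.67) and even a raw binary isosurface mesh by ~25 %; after staircase
  smoothing the measured area of digitized balls of radius 4–13 voxels is
  within about 3 % of the analytic value, always slightly above it, so
  sphericity stays in $(0.95, 1]$ for spheres.
* **Texture matrices.** GLCM: 13 unique 3D directions at distance 1,
  symmetric counts, *summed* over directions before normalization (the
  merged strategy; per-direction feature averaging is available via
  `glcm_aggregation = "average"`). GLRLM: runs per direction, features
  averaged over the 13 directions. GLZLM: zones are 26-connected
  components of equal level. NGLDM uses the classical neighbourhood
  grey-tone difference formulation over available in-mask 26-neighbours.
  All four matrix builders and all 31 feature formulas are checked exactly
  against an independent brute-force enumeration oracle in the test suite.

# The statistical engine

* **Cutpoint selection** (`maxstat_cutoff()`): candidate cutpoints are the
  observed marker values between the 10th and 90th percentiles (a standard
  minimal-group protection; both bounds configurable, minimum group size 3);
  each split `<= c` vs `> c` is scored by the log-rank chi-square and the
  maximizer returned, ties toward the smaller cutoff. The log-rank variant
  of maximal selection was chosen (over fixed-time 2×2 chi-squares) as the
  standard survival form. Because maximizing over many splits inflates the
  statistic, the naive chi-square p-value is optimistic; the improved
  Bonferroni-type p-value for maximally selected statistics is reported
  alongside (`p_corrected`), but downstream Cox p-values are *not*
  corrected — they mirror the conventional two-step practice and should be
  read accordingly.
* **Cox models** (`cox_fit()`): partial likelihood via `survival::coxph`
  with Efron tie handling; dichotomized covariates are coded 0 (`<=`
  cutoff) / 1 (`>` cutoff). Fewer than ten events per covariate triggers a
  warning (rule of thumb, not an error); non-convergence or a diverging
  coefficient (complete separation) is an explicit failure.
* **Harrell's C** (`harrell_c()`) is implemented in-package with the
  original pair conventions — usable pairs are those whose shorter time is
  an event (tied times usable only with discordant event status), risk
  ties count ½ — and cross-checked against `survival::concordance` on
  tie-free data. The confidence interval is a seeded percentile bootstrap
  over patients (1000 resamples by default). Pair counting is $O(n^2)$,
  intended for cohorts up to a few thousand.
* **Kaplan–Meier** (`km_estimate()`): product-limit estimator via
  `survival::survfit`; the reported median is the *earliest time with*
  $S(t) \le 0.5$ (survfit's convention of averaging the two flanking times
  when $S$ hits 0.5 exactly is deliberately not used), with the
  Brookmeyer–Crowley interval from inverting the pointwise survival CI.
  A queried horizon beyond follow-up returns the last step value flagged
  `extrapolated`.

# The scoring system

`scoring_rule()` fixes the design weights: 1 point per tumor factor
(TLG, first-order entropy), 2 points for the host factor (BM SUV), strict
`>` against the cutoffs (default 41.40 g, 3.40, 1.53 — values exactly at a
cutoff score 0). The weights are constants of the design, not fitted.
Totals pool into prognostic groups 0–2 / 3 / 4; over the eight indicator
combinations the attainable totals are exactly {0, 1, 2, 3, 4}.
`derive_rule()` either packages manual cutoffs or derives all three by
maximal selection; `evaluate_stratification()` reports per-group
Kaplan–Meier summaries, a categorical Cox model against the 0–2 reference,
Harrell's C of the total score, and the two predefined subgroup splits
(stage I–II vs III–IV; surgical resection vs other treatments). Empty
groups keep explicit `NA` markers.

# The synthetic generator

## Phantoms

`generate_phantom()` renders a sphere phantom: one tumor, six vertebral
bodies, a liver reference sphere, constant soft-tissue background,
optional additive Gaussian noise (clamped at 0). Defaults are chosen to
emulate a typical staging scan: 48×48×72 grid at 4 mm spacing, tumor
radius 15.5 mm (≈ 280 voxels ≈ 17.9 cm³, near a typical metabolic tumor
volume), tumor mean SUV 5 on background 0.5, vertebral mean SUV 1.74
(a typical cohort median), liver SUV 2, noise SD 0.05 SUV.

Tumor heterogeneity is a *spatially correlated multiplicative field*: a
Gaussian random field with configurable correlation length (default 8 mm)
is rank-transformed to a uniform multiplicative factor on
$[1-h,\,1+h]$, where $h$ is the heterogeneity level. Spatial correlation
matters because uncorrelated voxel noise barely moves matrix-based texture
features. The bounded-uniform form was chosen over a lognormal field after
observing that a heavy upper tail stretches the per-lesion maximum and
thereby *compresses* relative 64-level binning — entropy then responds
non-monotonically to $h$. With the bounded field, planted heterogeneity
and extracted first-order entropy are monotonically linked, which the test
suite asserts over 20 seeds at $h \in \{0, 0.5, 1\}$.

One global seed fans out into fixed per-component substreams (texture
field, noise), so enabling noise does not perturb the texture field.
Regions must be pairwise disjoint and the tumor must render at least 64
voxels; violations are errors naming the offending regions.

## Cohorts

`generate_cohort()` draws covariates matched to a typical 65-patient
staging cohort (marker medians 1.74 / 55.54 g / 3.40; stage distribution
9/43/29/19 %; 57 % surgical resection) and inverts an exponential
proportional-hazards model with planted log-hazard ratios for the
dichotomized markers (defaults 4.30, 2.37, 2.89), age > 65 and stage.
The exponential baseline was chosen for closed-form inversion and easy
medians. The default baseline hazard, 0.00188 events/month, is calibrated
so the *cohort-level* median OS is ≈ 14 months under the default planted
effects (solving $E[S(14.1)] = 0.5$ over the covariate distribution).

Censoring is independent exponential truncated at an administrative
horizon (default 61 months, a typical maximum follow-up). The exponential
rate is solved analytically from a target censoring fraction (default
28/65) given the realized subject-specific hazards, using
$P(\text{event}) = \frac{a}{a+c}(1 - e^{-(a+c)\tau})$. The horizon imposes
a floor on achievable censoring; a target below the floor produces a
warning and the floor is realized. Generated tables carry the planted
indicators and linear predictor so recovery is directly testable.

An optional `marker_correlation` couples the latent bone-marrow uptake
with the inflammation markers NLR/PLR; the default is 0 because no
generative link is established, only observed correlations.

## Screening registry

`synthetic_registry()` plants the five exclusion categories (no staging
PET; supportive care only; prior malignancy; uptake too low to delineate;
tumor < 64 voxels) into a screening registry;
`apply_eligibility_filter()` applies them *in listed order*, counting each
patient once at the first matching criterion — the tally convention for
multi-reason patients is not otherwise defined, and first-match is the
reproducible choice. The canonical configuration (97 records, sequential
tallies 6/14/3/4/5) leaves 65 eligible.

# Validation design and problem sizes

The test suite validates every stage against independent oracles:
brute-force enumeration for the adaptive threshold and all texture
matrices/features (exact agreement on random 4×4×4 arrays); analytic
limits (uniform histogram entropy 6 bits, energy 1/64; constant-image GLCM
entropy 0, energy 1; ball sphericity ≥ 0.95; TLG ≡ MTV × mean SUV);
`survival::survdiff` / the Cox score test for the log-rank scan; and
`survival::concordance` for Harrell's C.

Statistical recovery is tested at sizes where the assertion has adequate
power: cutpoint recovery at n = 400 (±0.1 around a planted 1.53);
Cox hazard-ratio recovery at n = 2000 averaged over 5 replicate cohorts
(a single fit's log-HR standard error is ≈ 0.056, so a ±10 % band on one
draw would be a coin-flip near its edges); 200-replicate unbiasedness and
coverage at n = 500; Kaplan–Meier median recovery at n = 5000;
null concordance over 100 replicates at n = 500. Cutpoint error is checked
to shrink with n over {100, 400, 1600}.

# What passing tests do and do not show

The phantom shares the measurement geometry, not the biology: spherical
lesions, piecewise-constant organs, stationary texture, Gaussian noise,
no partial-volume effect, no reconstruction artifacts, no respiratory
motion, no anatomical variability. The cohort model is exactly
proportional hazards with exponential baseline — real survival data are
neither. Passing tests therefore demonstrate that the *computations* are
correct and the *pipeline* recovers what was planted under its own
assumptions; they say nothing about clinical validity on real patients,
which requires external cohorts. Likewise the default cutoffs (41.40 g,
3.40, 1.53) are reference constants of the scoring rule, not quantities
re-derivable from synthetic data.

# Known limitations

* No DICOM input, PET reconstruction, attenuation or partial-volume
  modelling; volumes enter as NIfTI SUV grids with aligned masks.
* No wavelet/filtered-image features, CT-channel radiomics, or
  scanner harmonization.
* `harrell_c()` is $O(n^2)$ in memory and time.
* No time-dependent covariates or competing risks; proportionality is
  assumed, not tested.
* The cutpoint-selection p-value correction is reported but not
  propagated into downstream models.
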