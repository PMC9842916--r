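---
title: "Mapping subcortical stroke lesions to cortical structural change: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping subcortical stroke lesions to cortical structural change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis problem

After a subcortical ischemic stroke, the cerebral cortex changes slowly:
regions fed by the damaged fiber tracts thin (degeneration), while other
regions thicken or expand (reorganisation). `lesionmap` implements the
statistical machinery of a lesion-to-cortex mapping study of this process
in five connected stages, plus a seeded synthetic-cohort generator that
makes the whole chain testable without patient data:

1. **Slice-wise corticospinal-tract (CST) impairment.** For a binary
   lesion mask and a fiber-atlas subset (fibers of M1, premotor, SMA or S1
   origin), every axial slice with lesion-tract overlap contributes the
   ratio *overlap area / tract area in that slice*; the impairment
   percentage is the maximum ratio over slices (`impairment_percentage()`).
   The denominator is the tract's area *in the same slice*, not the whole
   tract volume: a focal capsular lesion can transect most of a tract's
   cross-section while touching a tiny fraction of its volume, and the
   slice-wise maximum captures exactly that. The whole-volume alternative
   is available behind `whole_volume = TRUE`. Areas are voxel counts,
   equivalent to mm² at constant in-plane resolution.

2. **Mass-univariate group mapping with cluster-extent correction.**
   `fit_pointwise_glm()` fits value ~ group + age + sex + scanner +
   measure-matched global covariate at every point of a 2D measure sheet;
   `monte_carlo_cluster_correct()` thresholds the t field two-sidedly at
   voxel p < .01, forms sign-specific 4-connected clusters and compares
   each extent with the null distribution of the maximum suprathreshold
   extent of smoothed Gaussian fields (FWHM 10 mm), with the
   (1 + k)/(N + 1) p estimator. `replicate_rois()` then refits the GLM on
   an independent replication sample inside each retained cluster and
   keeps same-sign points at p < .05 — a discovery-replication ROI design.

3. **ROI-level inference.** `ancova_three_group()` compares partial
   recovery (PR), complete recovery (CR) and healthy control (HC) groups
   with covariate adjustment and pairwise contrasts;
   `partial_correlation()` relates ROI measures to the whole-extremity
   Fugl-Meyer score (WE_FM, 0-100) and `cst_correlations()` to the four
   CST impairment percentages, each subset controlling the other three.
   `by_fdr()` implements the Benjamini-Yekutieli step-up with the harmonic
   factor c(m) = sum(1/i), valid under arbitrary dependence; it corrects
   the WE_FM, CST and longitudinal families.

4. **Voxel-based lesion-symptom mapping (VLSM).** `vlsm_map()` tests, at
   every voxel damaged in strictly more than 10% of patients, outcome ~
   lesion status + age + sex + scanner + lesion volume, corrects
   voxelwise with Benjamini-Hochberg FDR at q = .05 (Benjamini-Yekutieli
   selectable) and reports 6-connected clusters of strictly more than 10
   voxels with unweighted centroid and max-|t| peak in world mm.

5. **Longitudinal trajectories.** `fit_random_intercept()` fits
   y_ij = b0 + b1 t_ij + u_i + e_ij per group by REML: a common slope per
   group, subject-specific intercepts absorbing the repeated-measures
   correlation, missing visits handled by likelihood. Pairwise slope
   differences combine two independent group fits by a Wald z,
   (b1_a − b1_b)/sqrt(se_a² + se_b²), against the normal reference.
   `classify_pattern()` labels each ROI's evolution: **1** decline with a
   significant PR slope, both patient slopes negative; **2** increase in
   both patient groups, both significant; **3** significant increase only
   in CR; **4** divergent trajectories — opposite slope signs, both
   slopes and their difference significant. Rules are applied in the
   order 4, 1, 2, 3; all significance is BY-corrected at q = .05.

`run_pipeline()` executes all stages from one validated configuration
(`demo_run_config()`), writing stage tables and a JSON manifest, and the
numbered scripts under `analysis/` present the same workflow as a
narrative.

# The coordinate model

All volumes share a `grid_spec`: a diagonal affine with world coordinate
`origin + (voxel − 1) * voxel_size`. The default grid is 32³ voxels at
2 mm — a desk-scale stand-in for a standard-space brain at 1 mm — centred
so the mid-sagittal plane x = 0 separates the hemispheres; world x < 0 is
left (neurological convention, no flip). Voxel indices are 1-based
internally; every reported coordinate (cluster centroids, peaks, loci) is
world mm. Cortical surfaces are replaced by flat 64×64 measure sheets at
2 mm spacing: cluster-extent inference is identical on a sheet and a
tessellated surface, and the sheet keeps the Monte-Carlo machinery exact
and fast.

# What the synthetic cohorts emulate

`simulate_cohort()` draws, under one seed:

* **Lesions.** Ellipsoids (20-120 voxels) near a primary locus — the M1
  fiber column, the S1 fiber column, or a fiber-free "capsule" locus —
  plus, independently with probability 0.45, a smaller (40-90 voxel)
  second lesion at an off-tract "putamen" locus. Lesions are clipped at
  the mid-sagittal plane. The independence of the putamen lesion from the
  fiber class is deliberate: it keeps lesion-location effects orthogonal
  to the impairment percentages, so the CST correlation family stays
  specific. The three-way primary mix (0.35/0.3/0.35) keeps the M1 and S1
  impairments identifiable when each is partialled on the other.
* **Fiber atlas.** Four meandering two-voxel-thick columns per hemisphere
  spanning the upper three quarters of the z extent, mirrored across the
  midline, with base positions separated by more than the largest lesion
  radius so a lesion aimed at one tract cannot graze another.
* **Motor outcome.** WE_FM = clamp(100 + margin − 1.2·(M1 impairment) +
  noise) with margin 4 and noise SD 6; the clamp at 100 creates the point
  mass that defines complete recovery (CR, WE_FM = 100) versus partial
  recovery (PR, WE_FM < 100) and yields roughly 45% CR at the defaults.
* **Cortical measures.** Ten ROI-measure pairs (4 thickness, 3 surface
  area, 3 gray-matter volume; ipsilesional and one contralesional)
  generated as baseline + covariate effects (age, sex, scanner) +
  injected effects + group slope × months + subject random intercept +
  noise. Residual and intercept SDs both default to 0.15 measure units,
  giving an intraclass correlation of 0.5 — large enough that the
  random-intercept variance is identifiable at n ≈ 80. Injected effects:
  a putamen-lesion-coupled surface-area increase (+0.45) in the temporal
  pole (the VLSM target), impairment-proportional couplings of M1 fibers
  to precentral thickness (−0.40 at 100%) and S1 fibers to lingual
  thickness (+0.60 at 100%), and a PR-only postcentral deficit (−0.30).
* **Visits.** Nominal months 0.25, 1, 3, 7 (acute to chronic), each
  jittered uniformly by ±20% to mimic fluctuating acquisition times;
  cross-sectional cohorts use a single chronic visit at 12 months.
* **Longitudinal slopes.** Four designated ROIs realise the four
  evolution patterns: postcentral thickness −0.022 (PR) / −0.012 (CR)
  per month; lingual thickness +0.03/+0.06; frontal-pole thickness
  +0.002/+0.025; cingulate area −0.03 (PR) / +0.03 (CR); healthy controls
  are flat. The magnitudes give the BY-corrected slope tests roughly 3σ
  margins, matching a study in which the reported pattern ROIs are
  strongly, not marginally, significant.
* **Sheets.** Per-subject smoothed white noise (FWHM 10 mm, unit SD) plus
  square patient-vs-control patches (amplitude ±1.0, half-width 4) for
  the thickness and area sheets — the targets of the
  discovery-replication stage.

The generator returns its ground truth (loci, per-subject locus and
secondary-lesion flag, true impairments, effect and slope tables), so
every downstream test is closed-loop.

What the cohorts do **not** emulate: vascular lesion shapes, registration
error, cortical folding and surface geometry, scanner-specific smoothness
differences, dropout correlated with severity, and measurement error in
the clinical score beyond additive noise. Passing tests therefore
demonstrate the statistics are implemented and calibrated as specified,
not that the pipeline is robust to real-world artefacts.

# Numerical choices

* **REML.** The random-intercept likelihood is profiled to the variance
  ratio γ = σ²_b/σ²_e and optimised in log γ over [−14, 14] with
  tolerance 1e-10; the γ = 0 boundary is evaluated explicitly, so zero
  between-subject variance reduces exactly to OLS. Per-subject rank-one
  downdates give V⁻¹ in closed form; a noiseless cohort short-circuits to
  the exact line with zero variances. Estimates reproduce lme4 and the
  balanced-design ANOVA estimators to well below 1e-6.
* **Monte-Carlo null fields.** Simulated white noise is smoothed with a
  truncated (4σ), row-renormalised separable Gaussian kernel and
  standardised *pointwise* by the exact kernel-weight variance, then
  thresholded at the normal quantile whose exceedance probability equals
  the voxel threshold — the same exceedance rate the observed t-field has
  at its t quantile. Matching the exceedance rates, rather than reusing
  the t quantile on a Gaussian field, is what keeps the familywise error
  of the whole pipeline at its nominal level (measured 2-6% at nominal
  5% over 200 null cohorts).
* **Cluster p-values** use (1 + k)/(N + 1), so no cluster gets p = 0.
* **Connectivity** is face-only: 4-neighbour in 2D, 6-neighbour in 3D.
* **Strict thresholds.** "More than 10%" and "more than 10 voxels" are
  strict inequalities; a voxel damaged in exactly 10% of patients is
  excluded, a 10-voxel cluster is not reported.
* **Degenerate inputs.** Voxels lesioned in every subject are skipped
  with a warning (no contrast); fiber subsets with all-zero impairment
  are reported not-testable rather than erroring; empty seed masks yield
  empty ROI sets; the WE_FM draw is retried (cap 20) if a recovery
  stratum comes out empty.
* **Cohen's d** defaults to the covariate-adjusted form (ANCOVA contrast
  divided by residual SD) so d matches the reported contrast; the
  raw-value pooled-SD form is available (`adjusted_d = FALSE`).

# Design choices where the design was open

* **Separate mixed models per group** rather than one interaction model:
  per-group slope tests and cross-group Wald contrasts mirror reporting
  that treats each group's trajectory as its own fit. The contrast of two
  REML fits has no exact finite-sample reference, so the normal
  approximation is used; group sizes of 30+ make this adequate.
* **BH at the VLSM voxel level, BY for the correlation and slope
  families**: voxel-level lesion-symptom mapping conventionally uses the
  plain FDR step-up, while the harmonic-corrected BY is reserved for the
  smaller, arbitrarily dependent ROI families. Both are selectable.
* **Two-tailed voxel tests with sign-specific clustering** throughout.
* **Hemisphere-specific VLSM and correlation families, pooled-hemisphere
  sheet mapping**: ROI measures are coded ipsi/contralesional, so the
  sheet stage needs no left/right split, while lesion-anatomy analyses
  respect it.
* **Discovery/replication split** at 63% of patients with shared
  controls, mirroring a reuse-the-controls replication design.

# Problem sizes and operating characteristics

The packaged calibration studies (`eval_*`, re-run by
`scripts/acceptance.R` and the acceptance tests) use: 200 null lesion
cohorts of n = 60 for VLSM calibration; 50 cohorts of n = 120 with a
d = 1 putamen effect for localisation (criteria fix the effect size; the
cohort size is the package's choice); 200 null sheet cohorts of 40 + 40
with a 500-simulation extent null for familywise error; 2,000 draws of 50
uniform p-values for FDR control; 1,000 null ANCOVA data sets; 300
balanced cohorts of 40 × 4 visits for slope-CI coverage; 50 longitudinal
cohorts at generator defaults for pattern classification; and one full
demo pipeline (180 + 100 cross-sectional, 80 + 12 longitudinal subjects,
1,000 extent simulations). Typical results: null VLSM survival fraction
below 0.005, localisation ≥ 96%, FWER 2-6%, empirical FDR ≈ 0.01,
ANCOVA type-I error ≈ 5%, slope coverage ≈ 95%, pattern-4 classification
≥ 96%.

# Known limitations

* The toy grid and flat sheets ignore cortical geometry; smoothing and
  cluster extent on a real surface mesh require geodesic neighbourhoods.
* The Wald/normal inference for slope contrasts is asymptotic; very small
  groups (< 10 subjects) would need a parametric bootstrap.
* The Monte-Carlo null assumes stationarity and a known smoothness; real
  data would estimate smoothness from residuals.
* Binary atlases only; probabilistic fiber maps are out of scope.
* The generator's lesion classes are stylised; it is a test harness for
  the statistics, not a lesion simulator.
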