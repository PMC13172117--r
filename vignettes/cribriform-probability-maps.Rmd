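---
title: "Whole-prostate cribriform probability maps: model, assumptions, and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-prostate cribriform probability maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cribmap)
```

## The problem

Cribriform Gleason-pattern-4 growth (GP4Crib+) is an adverse histologic
feature of prostate cancer: its presence carries a markedly worse prognosis
than non-cribriform pattern-4, and its *absence* in grade-group-2 (GG2)
disease is an argument for managing intermediate-risk men with active
surveillance (AS) instead of immediate treatment (AT). Cribriform foci are,
however, easy to miss at biopsy. cribmap implements a noninvasive,
patient-level predictor of cribriform presence from diffusion MRI, and the
decision-analytic machinery to ask the clinically relevant question: *if AS
eligibility were extended to intermediate-risk men without predicted
cribriform growth, how would over- and undertreatment change?*

## The model

The predictor is deliberately minimal: a logistic regression on a single
radiomic feature, the 90th percentile of the apparent diffusion coefficient
(ADC) within a region,

$$\Pr(\text{GP4Crib+}) = \operatorname{logit}^{-1}\!\big(\beta_0 + \beta_1\,
\mathrm{ADC}_{p90}\big), \qquad \beta_1 < 0 .$$

Cribriform tissue is densely cellular, which restricts water diffusion, so
low p90 ADC raises the predicted probability: the slope is negative on any
data with this structure (`fit_crib_model()` asserts nothing about sign, but
the tests do). The percentile uses the linear-interpolation (type-7)
convention at fractional rank $0.9(n-1)$; this is stated explicitly because
percentile conventions differ across ecosystems and the feature feeds a
nonlinear model.

Region-level coefficients for a deployed clinical model are site-specific
and not distributed with the package. `fit_crib_model()` fits coefficients
from region samples (Newton–Raphson on the optionally L2-penalized binomial
likelihood, gradient-norm stop at $10^{-8}$; with one feature, complete
separation is exactly non-overlap of the two classes' feature ranges and is
reported as an error suggesting `l2 > 0`). `default_crib_model()` provides
illustrative coefficients ($\beta_0 = 9$, $\beta_1 = -0.01$ per
$10^{-6}\,\mathrm{mm^2/s}$, probability 0.5 at ADC 900) for demos; because
every downstream patient score is a monotone transform of the window
features, rank-based results such as AUROC do not depend on the particular
negative-slope coefficients used.

## From region model to whole-prostate map

The deployed model was conceived for histology-matched regions; cribmap
extends it to the whole gland with a multi-scale sliding window
(`sliding_window_map()`):

* Square in-plane windows of 5, 7, 9, 11 and 13 voxels slide with stride 1
  over every axial slice. Windows are two-dimensional by design: at typical
  prostate DWI geometry (~1 mm in-plane, 2.7–4 mm slices) an isotropic 3-D
  window of these sizes would be physically implausible. For fixed physical
  extents across heterogeneous resolutions, `windows_from_mm()` converts mm
  to odd voxel counts.
* A window is *valid* if it lies inside the slice and at least
  `min_mask_fraction` (default 0.5) of its voxels are in the prostate mask;
  its feature is the p90 over its in-mask voxels only. The boundary-handling
  fraction is a free parameter the source procedure leaves open; 0.5 keeps
  peripheral-zone coverage without letting windows be dominated by
  extra-prostatic tissue.
* **Maximum projection**: each voxel receives the maximum probability over
  all valid windows *covering* it (`aggregation = "cover"`, the default), so
  the most suspicious scale wins. The alternative reading — each window
  informs only its centre voxel, maximized over sizes
  (`aggregation = "center"`) — is also implemented; the covering windows are
  a superset of the centred ones, so cover-aggregated maps dominate
  center-aggregated maps voxel-wise, and both are checked against a
  brute-force window enumeration in the tests. Neither reading is endorsed
  as canonical.
* The patient-level score is the map maximum (`patient_score()`), and
  classification at a threshold is strict: a patient is predicted positive
  only when the score *exceeds* the threshold (`classify_patient()`).

Two useful monotonicity properties follow from the construction and are
tested: lowering any in-mask ADC value can only raise (never lower) map
values and the patient score when $\beta_1 < 0$; and adding a window size
can only raise cover-aggregated values.

## Mask preparation

Segmentation uncertainty at the gland boundary is absorbed by
`erode_mask()`: a one-voxel in-plane erosion (cylindrical structuring
element of height one slice; 4-connected cross by default, 8-connected
square as an option), applied only to slices whose upper and lower
neighbours also contain segmentation. Edge slices — where automated
segmentations are least trustworthy — therefore pass through unchanged
(default) or can be dropped outright (`restricted = "drop"`); whether the
original procedure kept or excluded them is not determinable from its
description, so both are provided with "keep" as the default. Erosion is
intentionally not idempotent: a second call erodes interior slices further.
`resample_mask_to_grid()` provides nearest-neighbour coregistration onto the
ADC grid under a shared-origin, axis-aligned convention.

## Upstream: segmented IVIM fitting

ADC maps are produced from multi-b-value DWI by the two-step segmented
intravoxel-incoherent-motion fit (`fit_segmented_ivim()`): a log-linear
least-squares fit over $b \ge 200\,\mathrm{s/mm^2}$ (configurable) yields
the tissue diffusion coefficient $D$; extrapolating to $b = 0$ and
comparing with the measured $S(0)$ yields the perfusion fraction
$f = 1 - S_0'/S(0)$, clipped to $[0,1]$. The pseudo-diffusion coefficient
$D^*$ is never estimated — the downstream model uses only ADC, so the
minimal estimator suffices. Very high b-values (> 1000 s/mm², present in
some acquisitions) are excluded by default to avoid non-Gaussian diffusion
bias. Degenerate voxels (non-positive signals) are flagged invalid, never
silently zeroed. The forward model `simulate_ivim_signal()` exists so the
fitter can be validated by round trip: in the noiseless regime with a fast
perfusion compartment ($f e^{-bD^*} < 10^{-6}$ at all fitted b), $D$ is
recovered within 1% and $f$ within 0.01.

## The decision framework

Patients are risk-stratified with the standard five-tier Cambridge
Prognostic Groups (`assign_cpg()`; the criteria are an external clinical
standard, restated in the function documentation). Three allocation
scenarios are modelled (`allocate()`):

* **reference** — guideline benchmark, no model: CPG-1 to AS, everyone else
  to AT;
* **cpg12** — CPG-1 to AS by rule; CPG-2 to AT iff the model score exceeds
  the threshold;
* **cpg123gg2** — as cpg12, with CPG-3 patients whose biopsy showed only
  GG2 also routed through the model.

Against prostatectomy ground truth, every allocated patient falls in exactly
one of six categories (`categorize_outcomes()`): correctly in AS (no
cribriform, GG < 3); correctly in AT (cribriform, or GG ≥ 3); falsely in AS
with a small (< 1.5 mm) or large (≥ 1.5 mm) missed cribriform focus —
1.5 mm being the nominal MRI detection limit; falsely in AS with GG ≥ 3
despite no cribriform; and falsely in AT. Undertreatment is the sum of the
three falsely-in-AS categories, overtreatment is falsely-in-AT, and
appropriate management the two correct categories. Treating
cribriform-negative GG ≥ 3 patients in AT as *correctly* treated is a
deliberate design choice: it is the only reading under which the published
count-level accounting of this framework is arithmetically self-consistent,
and it matches the clinical logic that GG ≥ 3 disease belongs in AT. (Some
narrative descriptions of this framework attach "overtreatment" and
"undertreatment" to the opposite bar colours of their own figures; the
mapping here follows the figure legends and the printed percentages.)

`run_scenario()` sweeps thresholds and enforces the partition invariant
(counts sum to the cohort) before returning. Because the threshold rule is
strict, raising the threshold can only move patients from AT to AS, so
overtreatment is non-increasing and undertreatment non-decreasing along a
sweep — a property tested on random cohorts.

## The fixture cohort

`fixture_cohort()` returns a fixed, synthetic 127-record cohort used by the
examples, tests and the acceptance script: CPG-1 n = 26, CPG-2 n = 72,
CPG-3(GG2) n = 29; cribriform prevalence 41% (52/127, of which 3 in CPG-1
and 36 in CPG-1+2); 22 patients with prostatectomy GG ≥ 3 (0/12/10 across
the groups). The joint cribriform × GG cells per group (documented in the
function help) are the unique solution of the linear constraints that the
group marginals impose together with the reference-scenario accounting
rates the framework must reproduce (61% appropriate in both nested cohorts,
18% correctly in AS, 36% overtreatment in CPG-1+2). Biopsy-GG, T-stage and
prostatectomy-GG assignments within cells reproduce the full marginal
distributions; where the marginals underdetermine a joint assignment the
choice is arbitrary and fixed in code. Cribriform focus sizes are not part
of the constraint system; crib-positive records default to 6 mm (≥ 1.5 mm,
so none fall in the small-focus category) and the value is a parameter.

## Synthetic imaging cohorts

`generate_phantom()`/`generate_cohort()` provide the imaging ground truth
the real study cannot ship. Defaults — chosen once as the package's study
conditions — are: 48 × 48 × 14 grids at 1.1 × 1.1 × 3 mm (within typical
prostate DWI resolution and slice-thickness ranges); an ellipsoidal gland of
roughly 40 × 34 × 30 mm (± 5% per patient); Gaussian class ADC
distributions of 1400 ± 200 (background), 1000 ± 150 (GP3), 900 ± 150
(GP4Crib−) and 700 ± 120 (GP4Crib+), in 10⁻⁶ mm²/s — values that encode
the published *sign* of the ADC–cribriform association with plausible
prostate magnitudes, not a validated fit to any cohort; and 1–3 ellipsoidal
lesions per gland with maximum in-plane diameters of 6–12 mm, the size
range of MRI-conspicuous index lesions (sub-1.5-mm foci can be requested
explicitly for undertreatment-size experiments but would be invisible to
windows ≥ 5 voxels, and are therefore not part of the default imaging
conditions). Lesions are placed by rejection sampling fully inside the
gland without overlap; placement failure after 200 attempts is an error,
never a silent truncation. Measurement noise (`"gaussian"` or `"rician"`,
the latter as the magnitude of a complex Gaussian perturbation) is off by
default since the class spreads already model tissue heterogeneity.
Everything is reproducible bit-for-bit from a seed.

What the phantoms deliberately do **not** model: zonal anatomy, T2-weighted
contrast, lesion-shape irregularity, spatial noise correlation, partial
volume at lesion borders, scanner/field-strength effects. Passing the
end-to-end tests therefore demonstrates that the *pipeline* recovers
patient-level signal that is present by construction — it is evidence about
the code, not about clinical performance on real MRI.

## Numerical choices and degenerate inputs

* Percentile: type 7; windows use in-mask voxels only; a window needs ≥ 1
  in-mask voxel regardless of the fraction rule.
* The sliding-window engine is compiled (Rcpp) for tractability at cohort
  scale; its exactness is pinned to an R brute-force enumeration in the
  tests rather than trusted.
* Logistic fitting optimizes on an internally standardized feature for
  conditioning and maps coefficients back exactly; step-halving keeps the
  penalized likelihood monotone.
* Empty masks error; masks too thin to admit any valid window yield an
  empty-validity map with a warning, and `patient_score()` on such a map
  errors rather than inventing a score.
* Bootstrap resamples that lose a class are skipped and counted; more than
  50% degenerate resamples aborts. Percentile (not BCa) intervals, so the
  point estimate is not guaranteed to lie inside — this is documented
  behaviour, not a bug.
* All simulation sizes used in the tests (120-patient discrimination
  cohort, 10 × 60-patient null controls, n = 5000 coefficient recovery,
  n = 2000 binormal AUROC check) were chosen to give comfortable
  statistical margins at interactive runtimes.

## Known limitations

* The acceptance-grade evidence is count-level (fixture accounting) and
  property-level (oracle equivalence, parameter recovery, synthetic
  discrimination). Real-cohort performance numbers (AUROC ≈ 0.6–0.7,
  threshold-specific over/undertreatment shifts) require the original MRI
  data and coefficients, which are not public, and are out of scope.
* Two published AS-eligibility percentages round inconsistently with their
  own counts (26/98 and 26/127 versus "26%"/"21%" baselines); the package
  reports `as_eligible_pct` raw and takes no position on the discrepancy.
* The segmented-IVIM variant of the original acquisition chain is cited but
  not specified there; equivalence with that exact implementation cannot be
  asserted, only with the standard two-step estimator implemented here.

## A 60-second tour

```{r tour, eval = FALSE}
ph <- generate_phantom(phantom_config(),
                       record = list(crib_positive = TRUE), seed = 7)
pmap <- sliding_window_map(ph$adc, erode_mask(ph$mask), default_crib_model())
patient_score(pmap)

fx <- fixture_cohort()
run_scenario(filter_cpg_group(fx, "cpg12"), scenario = "reference")
```

The `analysis/` directory runs the same machinery as a five-step narrative
workflow (simulate → map → evaluate → decision scenarios → IVIM recovery),
writing its tables under `results/`.
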