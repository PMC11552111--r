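---
title: "Intracranial metabolic scoring: models, generators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intracranial metabolic scoring: models, generators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imscore)
```

## The problem

Primary CNS lymphoma (PCNSL) responds to methotrexate-based induction
chemotherapy, but end-of-therapy MRI struggles to separate residual tumour
from scar, and a binary "PET positive/negative" read gives no graded risk.
Two five-level visual scales address this on end-of-therapy FDG-PET:

* the **Deauville score (DS)**, standard in systemic lymphoma, compares the
  hottest residual lesion to the mediastinal blood pool and the liver
  (DS 5 when `SUV_lesion > 2 * SUV_liver` or a new lesion appears);
* the **intracranial metabolic score (IMS)** replaces the body references —
  unavailable on brain-only PET/MR — with intracranial ones: cerebrospinal
  fluid, white matter and gray matter. IMS 1 is no residual uptake; 2 is
  above CSF but below white matter; 3 is similar to white matter; 4 is
  above white matter but at most gray matter; 5 is above gray matter or a
  new lesion.

`imscore` implements this pair of scales as a tested pipeline: a synthetic
cohort and digital-phantom generator, SUV quantification with rule-based
reference ROI placement, score assignment, and the downstream prognostic
statistics (Kaplan–Meier, log-rank, Cox proportional hazards, chi-square
cohort comparison, contingency reconstruction, diagnostic metrics and
ordinal AUC). No patient data ship with the package; every analysis is
exercised end-to-end on simulated cohorts whose statistical structure
matches what the method assumes.

## Score assignment

Scores are assigned from the patient's hottest lesion SUVmax `L` against a
per-patient reference panel. Two conventions quantify the visual wording,
both configurable and both declared conventions rather than facts about
the scales:

* **The IMS 3 band.** "Similar to white matter" is a symmetric relative
  band `[(1 - b) WM, (1 + b) WM]` with `b = 0.10` by default
  (`scoring_tolerances()`). The band partitions the half-line: every
  nonnegative `L` maps to exactly one level provided `CSF < (1 - b) WM`;
  a panel violating that is rejected as degenerate rather than silently
  mis-banded.
* **Ties go to the lower score**, reading the strict "greater than" in the
  level definitions literally: `L = GM` is IMS 4, `L = 2 * liver` is DS 4.

The patient-level score uses the maximum over lesions, because any single
lesion above a reference drives visual positivity. A new lesion forces
level 5 on both scales regardless of `L`. On PET/MR the DS is refused with
an explicit "inapplicable" error: the panel has no liver or mediastinal
blood pool.

## The synthetic cohort generator

`simulate_covariates()` draws demographics and risk factors with marginal
prevalences matching a published end-of-therapy PET/CT PCNSL cohort (53%
male, age centred in the late fifties, half ECOG > 1, 55% multifocal
disease, roughly a third each superficial/deep/both lesion sites). The two
standard prognostic indices are recomputed from the covariates:
IELSG (count of age > 60, ECOG > 1, elevated LDH, elevated CSF protein,
deep lesions; grouped 0–1 vs 2–3, with counts of 4–5 folded into the high
group) and the three-class MSKCC index (0: age ≤ 50; 1: age > 50 and
KPS ≥ 70; 2: age > 50 and KPS < 70) — the only mapping consistent with
three printed classes given its two factors.

`simulate_true_scores()` assigns the underlying response category from a
configurable distribution; the defaults are the observed score
distributions (8/9/11/5/5 over IMS 1–5 of 38 on PET/CT; 10/9/12/9/5 of 45
on PET/MR). IMS 1 patients carry no lesions; 30% of IMS 5 patients are
5 by virtue of a new lesion.

`simulate_outcomes()` uses the simplest model satisfying the proportional
hazards assumption the Cox analysis makes: exponential PFS with hazard

```
h(t) = h0 * exp(log_hr_ims45 * 1[IMS >= 4] + log_hr_ims5_extra * 1[IMS = 5])
```

with independent exponential dropout truncated at an administrative
horizon. Defaults (`hazard_config()`): `h0 = log(2)/949` per day, placing
the low-score median PFS near the published 31.2 months;
`log_hr_ims45 = log(9.04)`, the published multivariate hazard ratio for
IMS 4–5 vs 1–3; dropout scale 3 years with a 5-year horizon, echoing the
published ~34.6-month median follow-up; and zero extra hazard for IMS 5
(the published IMS 5 contrast is not separately calibrated). OS is
constructed as PFS plus an exponential post-progression survival draw
(median 180 days) for progressors and equals the censoring time otherwise
— independent OS draws would violate `os_time >= pfs_time`, which this
construction enforces by design.

Every patient owns a random substream derived by hashing the patient id
and stage name with the master seed, so growing a cohort leaves existing
patients' draws untouched. The combined seed is passed through four
Lehmer-congruential scrambling rounds before seeding the RNG: nearby
(master, id) pairs must map to well-separated generator states, and
Mersenne-Twister initialisation alone does not decorrelate near-identical
seeds (without the scrambling, replicate Cox estimates are visibly
underdispersed relative to their asymptotic standard errors).

## The digital phantom

`simulate_phantom()` rasterises an analytic geometry on an isotropic grid
(default 2 mm, 128³ head): a spherical white-matter core inside a
gray-matter shell, two ellipsoidal lateral ventricles, spherical lesions in
the white matter lateral to the ventricles (multiple lesions on a ring, all
in one hemisphere), and — in PET/CT mode — a torso slab holding a liver
ellipsoid and a descending-aorta cylinder. This is deliberately not an
anatomical brain: it is sufficient for the ROI-placement and SUV logic the
package must exercise, and avoids any atlas dependency.

Per-patient reference SUVmax targets are drawn from normal distributions
truncated at 0.1 with the calibrated moments (gray matter 9.45 ± 2.01,
liver 2.96 ± 0.42, white matter 2.81 ± 0.58, mediastinal blood pool
1.80 ± 0.36, CSF 1.50 ± 0.34 — pooled PET/CT values; whether PET/MR
reference values differ is not established, so the same calibration is
used for both modalities and remains configurable). Structures within a
patient share a common uptake factor (pairwise correlation 0.5),
reflecting shared dose, glucose and scanner effects; independent draws
would make ~5% of panels degenerate (CSF at 90% of white matter), which
real panels are not. Panels with CSF above 85% of white matter are
redrawn — the 0.05 margin below the scoring threshold leaves headroom for
measurement noise.

Lesion uptake is drawn uniformly from the central 60% of the SUV band the
patient's true IMS implies relative to their own panel, so blur and noise
rarely push a lesion across a score boundary. SUV targets convert to
activity by inverting the SUV definition
(`SUV = activity [mCi/mL] * weight [g] / dose [mCi]`); multiplicative
Gaussian voxel noise (CV 5%) is applied and then smoothed by the Gaussian
point-spread blur (FWHM 4 mm, FFT-domain separable filter) — noise arises
in acquisition, and reconstruction smoothing acts on noisy data. With
both set to zero the plateau inside each structure equals its target
exactly, which is the round-trip property the quantification tests pin
down to machine precision.

## Quantification

`suv_field()` applies the SUV formula elementwise (units fixed at mCi and
grams internally; readers convert Bq-based inputs). Reference ROIs follow
the published rules: spheres of at least 1 cm for gray matter, white
matter and ventricular CSF, a 3 cm sphere in the liver, and a 1.5 cm
cylinder over contiguous slices of the descending aorta with wall voxels
excluded by one-voxel erosion. The "drawn as large as possible" manual
placement is made reproducible by centring each ROI at the structure's
deepest interior point — the argmax of the Euclidean distance transform
(separable squared-distance transform computed on the structure's bounding
box), ties broken at the lowest linear voxel index. Gray- and white-matter
ROIs go to the hemisphere contralateral to the uptake-weighted lesion
centroid (either hemisphere when there is no lesion), with the hemisphere
defined by the sign of x relative to the grid's midsagittal plane. SUVmax
(never mean or peak) is extracted everywhere.

Two readers' quantitative reconciliation is not modelled: placement is
deterministic, and `simulate_second_reader()` instead perturbs assigned
scores (keep with probability `agreement`, else shift one level) to
exercise the inter-rater kappa machinery.

## Statistics

Kaplan–Meier, log-rank and Cox fits are delegated to the `survival`
package behind thin validating wrappers; the test suite checks them
against independent oracles (empirical survival without censoring, a hand
hypergeometric tabulation, brute-force partial-likelihood maximisation)
rather than trusting either implementation alone. Conventions:

* **Cox ties: Breslow by default** (the default of the commercial
  statistics package the published analysis used), Efron available; both
  agree to 1e-8 on tie-free data. Wald 95% CIs and p-values; monotone
  likelihoods (all events in one group) are flagged "not available" with a
  diagnostic instead of reporting a spuriously finite hazard ratio.
* **Chi-square: uncorrected Pearson.** The published cohort-comparison
  p-values (0.047 for IELSG, 0.949 for sex) are reproduced by the
  uncorrected statistic and not by the Yates-corrected one, so the
  correction is off by default with a flag.
* **Diagnostic metrics** report percentages at one decimal and the
  two-point trapezoidal AUC `(sensitivity + specificity)/2` at three
  decimals, matching the published precision. Zero-denominator metrics are
  undefined (`NA`), never zero. The published dichotomised AUCs are
  exactly the two-point values, which is the identity the acceptance
  checks rely on.
* **Contingency reconstruction.** Published diagnostic tables are inverted
  from their marginals (cohort size, events, score-positives) plus one
  printed anchor metric; the integer table is unique, and reconstruction
  refuses anchors it cannot reproduce to the printed precision. One
  published cell (PET/MR, IMS 1–4 vs 5, OS, NPV) is internally
  inconsistent with its own column — the unique table implies 95.0 where
  92.5 (that column's PFS value) is printed — and the package reports the
  table-implied value.
* **Ordinal AUC** is the tie-corrected rank statistic with the
  Hanley–McNeil asymptotic CI. No multiple-testing adjustment is applied
  anywhere, matching the published analysis.

## Problem sizes and what the tests show

The suite verifies: exact reproduction of the published contingency-derived
metrics and chi-square p-values; parameter recovery for the
proportional-hazards generator (200 replicates of n = 2000 cohorts:
mean log HR within Monte-Carlo error of log 9.04, Wald coverage within
3 points of 95%); the 5% size of the null log-rank test over 1000
replicates; generator calibration against the reference moments within
3 standard errors at n = 1000 panels; and exact phantom round trips at
zero noise. Phantom-backed tests run on a reduced grid (48³ head at
2.5 mm with proportionally smaller structures) — quantification cost
grows with voxel count while the ROI and scoring logic do not, so the
compact grid exercises the same code paths.

Published multivariate hazard-ratio tables and the reader-agreement kappas
(0.910/0.958) are **not** reproduced numerically: they require
patient-level survival data and rater-level reads that were never
published. The hazard-ratio criterion is replaced by the parameter-recovery
property above; the kappa machinery is exercised against a simulated
second reader instead.

## Limitations

The phantom is analytic, not anatomical: no partial-volume correction, no
scanner or reconstruction physics (OSEM/TOF/PSF modelling), no MRI
sequences, and lesion masks are inputs to quantification rather than
segmented from images. Outcome generation is exponential
proportional-hazards with independent censoring — adequate for testing
estimators that assume exactly that, and silent on model misspecification.
Passing tests therefore demonstrate the pipeline's internal correctness
and calibration, not clinical performance on real scans.
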