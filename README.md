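# imscore

Response assessment for primary CNS lymphoma (PCNSL) from end-of-therapy
FDG-PET, built around the five-level **intracranial metabolic score
(IMS)** and the standard **Deauville score (DS)**, with the full
prognostic toolkit needed to evaluate them.

## Why

After induction chemotherapy, PCNSL patients need a graded, reproducible
read of residual disease. The Deauville score compares the hottest
residual lesion to the mediastinal blood pool and liver — references that
do not exist on brain-only PET/MR. The IMS replaces them with intracranial
references (cerebrospinal fluid, white matter, gray matter):

| Level | IMS (references: CSF, WM, GM)        | DS (references: MBP, liver)          |
|-------|--------------------------------------|--------------------------------------|
| 1     | no residual uptake                   | no residual uptake                   |
| 2     | > CSF, < white matter                | ≤ mediastinal blood pool             |
| 3     | ≈ white matter                       | > mediastinum, ≤ liver               |
| 4     | > white matter, ≤ gray matter        | > liver, ≤ 2 × liver                 |
| 5     | > gray matter and/or new lesion      | > 2 × liver and/or new lesion        |

SUV is computed as `activity (mCi/mL) × body weight (g) / injected dose
(mCi)`; patients are scored on the maximum lesion SUVmax, ties resolve to
the lower level, and "similar to white matter" is a configurable ±10%
band.

The package provides, as pipe-friendly tibble-in/tibble-out functions:

* a **synthetic cohort generator** (covariates, IELSG and MSKCC indices,
  true score categories, proportional-hazards PFS/OS outcomes) and a
  **digital PET phantom** (analytic head ± torso geometry, calibrated
  reference uptake — gray matter 9.45 ± 2.01 SUVmax, liver 2.96 ± 0.42,
  white matter 2.81 ± 0.58, mediastinum 1.80 ± 0.36, CSF 1.50 ± 0.34 —
  PSF blur, voxel noise, NIfTI-1 I/O);
* **quantification**: rule-based reference ROI placement (≥ 1 cm
  spheres for GM/WM/CSF placed contralateral to the lesions at the
  structure's deepest interior point, 3 cm liver sphere, 1.5 cm aorta
  cylinder with wall exclusion) and SUVmax extraction;
* **scoring**: `assign_ims()`, `assign_ds()`, published grouping schemes,
  Cohen's kappa;
* **prognostics**: Kaplan–Meier (`km_estimate()`), log-rank
  (`logrank_test()`), Cox PH with Breslow/Efron ties (`cox_fit()`, with
  broom-style `tidy()`/`glance()` and `autoplot()`), uncorrected Pearson
  chi-square, diagnostic metrics with the two-point AUC identity
  `(sens + spec)/2`, reconstruction of published 2×2 tables from their
  marginals, and ordinal ROC AUC.

## Worked example

```r
library(imscore)

report <- run_pipeline(pipeline_config(n = 38, seed = 7))
report
#> <ims_report> PET_CT cohort, n = 38, seed = 7
#>   DS applicable
#>   IMS distribution:
#>
#>  1  2  3  4  5
#>  8  6 14  7  3
#>   log-rank (IMS groupings):
#>   endpoint     scheme scale statistic df  p.value
#> 1      pfs       five   IMS     26.13  4 2.97e-05
#> 2      pfs 1-3_vs_4-5   IMS     25.44  1 4.56e-07
#> 3      pfs   1-4_vs_5   IMS      7.13  1 7.59e-03
#> 4      pfs  1-2_3-4_5   IMS      8.40  2 1.50e-02
#> ...

mean(report$cohort$ims == report$cohort$true_ims)
#> [1] 0.9736842
```

One call simulated 38 patients, rendered and quantified one digital
phantom each (blur and noise on), assigned IMS and DS, and ran the
survival analysis. The assigned IMS recovered the generating category for
37/38 patients (one borderline IMS 2 lesion crossed into the
white-matter band under noise), and higher scores separate progression-free
survival sharply — the 1–3 vs 4–5 dichotomy here gives a log-rank
chi-square of 25.4 on 1 df.

Published contingency tables can be reconstructed and checked directly:

```r
reconstruct_contingency(38, 12, 10, c(sensitivity = 66.7)) |>
  diagnostic_metrics()
#> # A tibble: 1 × 9
#>      tp    fp    fn    tn sensitivity specificity   ppv   npv   auc
#>   <dbl> <dbl> <dbl> <dbl>       <dbl>       <dbl> <dbl> <dbl> <dbl>
#> 1     8     2     4    24        66.7        92.3  80.0  85.7 0.795
```

A thin CLI wraps the same functions
(`inst/cli/imscore simulate-cohort | score | analyze | run-all`).

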