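Package: imscore
Title: Intracranial Metabolic Scoring for End-of-Therapy Brain FDG-PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Response assessment for primary central nervous system lymphoma
    from end-of-therapy FDG-PET using the five-level intracranial metabolic
    score (IMS, referenced to cerebrospinal fluid, white matter and gray
    matter) and the Deauville score (DS, referenced to mediastinal blood pool
    and liver). Provides a synthetic-cohort and digital-phantom generator,
    SUV quantification with rule-based reference ROI placement, score
    assignment with configurable banding, and the downstream prognostic
    toolkit: Kaplan-Meier estimation, log-rank tests, Cox proportional
    hazards models, chi-square cohort comparison, contingency-table
    reconstruction from published marginals, and diagnostic metrics
    (sensitivity, specificity, predictive values, AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
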