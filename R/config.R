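#' Reference-structure SUVmax calibration
#'
#' Mean and standard deviation of the SUVmax of each normal reference
#' structure used by the IMS and Deauville scales. Defaults are the pooled
#' end-of-therapy values observed on PET/CT: gray matter 9.45 +/- 2.01,
#' liver 2.96 +/- 0.42, white matter 2.81 +/- 0.58, mediastinal blood pool
#' 1.80 +/- 0.36, cerebrospinal fluid 1.50 +/- 0.34. Reference SUVmax values
#' are drawn per patient from normal distributions with these moments,
#' truncated below at `lower` to keep them positive.
#'
#' Within a patient the structure values share a common uptake factor
#' (correlation `rho` between any two structures), reflecting the shared
#' dose, glucose and scanner effects seen in real panels; panels where the
#' CSF value reaches 90% of the white-matter value (which would leave no
#' room for the residual-uptake bands between them) are redrawn.
#'
#' @param gm,wm,csf,liver,mediastinum Length-2 numeric `c(mean, sd)` per
#'   structure, in SUV units.
#' @param lower Lower truncation bound for the per-patient draws (SUV).
#' @param rho Common-factor correlation between structures within a
#'   patient, in `[0, 1)`.
#' @return An object of class `reference_calibration`: a tibble with columns
#'   `structure`, `mean_suv`, `sd_suv`.
#' @examples
#' reference_calibration()
#' @export
reference_calibration <- function(gm = c(9.45, 2.01),
                                  wm = c(2.81, 0.58),
                                  csf = c(1.50, 0.34),
                                  liver = c(2.96, 0.42),
                                  mediastinum = c(1.80, 0.36),
                                  lower = 0.1,
                                  rho = 0.5) {
  vals <- list(GM = gm, WM = wm, CSF = csf, liver = liver,
               mediastinum = mediastinum)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 2 || !is.numeric(v) || v[1] <= 0 || v[2] < 0) {
      config_error(sprintf(
        "calibration for %s must be c(mean, sd) with mean > 0, sd >= 0", nm))
    }
  }
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    config_error("`rho` must be in [0, 1)")
  }
  out <- tibble(
    structure = names(vals),
    mean_suv = vapply(vals, `[`, numeric(1), 1),
    sd_suv = vapply(vals, `[`, numeric(1), 2)
  )
  structure(out, lower = lower, rho = rho,
            class = c("reference_calibration", class(out)))
}

#' Survival-outcome generator configuration
#'
#' Parameters of the proportional-hazards outcome model used by
#' [simulate_outcomes()]. Progression-free survival times are exponential
#' with hazard `baseline_hazard * exp(log_hr_ims45 * 1[IMS >= 4] +
#' log_hr_ims5_extra * 1[IMS = 5])`, censored by independent exponential
#' dropout truncated at an administrative horizon. Overall survival is the
#' progression time plus an exponential post-progression survival draw for
#' progressors, and administratively censored otherwise.
#'
#' Defaults place the median PFS of the low-score group near 31 months, use
#' a hazard ratio of 9.04 for IMS 4-5 versus 1-3, a dropout time scale of
#' three years truncated at a five-year horizon, and a six-month median
#' post-progression survival.
#'
#' @param baseline_hazard Per-day PFS hazard of the IMS 1-3 group.
#' @param log_hr_ims45 Log hazard ratio applied when IMS >= 4.
#' @param log_hr_ims5_extra Additional log hazard ratio applied when IMS = 5.
#' @param censor_rate Per-day rate of the exponential dropout process
#'   (0 means administrative censoring only).
#' @param admin_horizon Administrative censoring horizon, days.
#' @param post_progression_hazard Per-day hazard of death after progression.
#' @return A list of class `hazard_config`.
#' @examples
#' hazard_config(log_hr_ims45 = log(9.04))
#' @export
hazard_config <- function(baseline_hazard = log(2) / 949,
                          log_hr_ims45 = log(9.04),
                          log_hr_ims5_extra = 0,
                          censor_rate = 1 / 1095,
                          admin_horizon = 1825,
                          post_progression_hazard = log(2) / 180) {
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0) {
    config_error("`baseline_hazard` must be > 0")
  }
  if (!is.numeric(admin_horizon) || admin_horizon <= 0) {
    config_error("`admin_horizon` must be > 0")
  }
  if (censor_rate < 0) config_error("`censor_rate` must be >= 0")
  if (post_progression_hazard <= 0) {
    config_error("`post_progression_hazard` must be > 0")
  }
  structure(list(
    baseline_hazard = baseline_hazard,
    log_hr_ims45 = log_hr_ims45,
    log_hr_ims5_extra = log_hr_ims5_extra,
    censor_rate = censor_rate,
    admin_horizon = admin_horizon,
    post_progression_hazard = post_progression_hazard
  ), class = "hazard_config")
}

#' Digital phantom geometry
#'
#' Analytic geometry of the digital head (and optional torso) phantom: a
#' spherical white-matter core wrapped in a gray-matter shell, two
#' ellipsoidal lateral ventricles, spherical lesions inside the white
#' matter, and -- for PET/CT -- a torso slab holding a liver ellipsoid and a
#' descending-aorta cylinder. All lengths are millimetres on an isotropic
#' voxel grid.
#'
#' The `"compact"` preset keeps clinically plausible structure sizes on a
#' coarser, smaller grid; it is the geometry used throughout the test suite
#' and examples because quantification cost grows with voxel count while the
#' ROI and scoring logic do not.
#'
#' @param preset `"default"` (128^3 head at 2 mm, 80-slice torso) or
#'   `"compact"` (64^3 head at 2.5 mm, 32-slice torso).
#' @param voxel_size Isotropic voxel edge, mm.
#' @param head_shape Head grid dimensions, voxels (length 3).
#' @param torso_slices Axial slices appended below the head in PET/CT mode.
#' @param wm_radius,gm_outer_radius White-matter core radius and outer
#'   gray-matter shell radius, mm.
#' @param ventricle_offset_x Lateral offset of each ventricle centre, mm.
#' @param ventricle_semiaxes Ventricle ellipsoid semi-axes, mm (length 3).
#' @param lesion_radius Lesion sphere radius, mm.
#' @param liver_semiaxes Liver ellipsoid semi-axes, mm.
#' @param liver_offset_x Lateral offset of the liver centre, mm.
#' @param aorta_radius,aorta_offset_x Descending-aorta cylinder radius and
#'   lateral offset, mm.
#' @param psf_fwhm Full width at half maximum of the Gaussian point-spread
#'   blur, mm (0 disables).
#' @param noise_cv Coefficient of variation of multiplicative voxel noise
#'   (0 disables).
#' @return A list of class `phantom_geometry`.
#' @examples
#' phantom_geometry("compact")
#' @export
phantom_geometry <- function(preset = c("default", "compact"),
                             voxel_size = NULL,
                             head_shape = NULL,
                             torso_slices = NULL,
                             wm_radius = 55,
                             gm_outer_radius = 75,
                             ventricle_offset_x = 14,
                             ventricle_semiaxes = c(10, 26, 10),
                             lesion_radius = 7,
                             liver_semiaxes = c(55, 40, 28),
                             liver_offset_x = 40,
                             aorta_radius = 12,
                             aorta_offset_x = -30,
                             psf_fwhm = 4,
                             noise_cv = 0.05) {
  preset <- match.arg(preset)
  if (preset == "compact") {
    voxel_size <- voxel_size %||% 2.5
    head_shape <- head_shape %||% c(64, 64, 64)
    torso_slices <- torso_slices %||% 32
  } else {
    voxel_size <- voxel_size %||% 2
    head_shape <- head_shape %||% c(128, 128, 128)
    torso_slices <- torso_slices %||% 80
  }
  radii <- c(wm_radius, gm_outer_radius - wm_radius, ventricle_semiaxes,
             lesion_radius, liver_semiaxes, aorta_radius)
  if (any(radii <= 2 * voxel_size)) {
    config_error(
      "all structure radii/semi-axes must exceed 2 * voxel_size")
  }
  if (gm_outer_radius <= wm_radius) {
    config_error("`gm_outer_radius` must exceed `wm_radius`")
  }
  if (length(head_shape) != 3 || any(head_shape < 8)) {
    config_error("`head_shape` must be 3 grid dimensions >= 8")
  }
  if (gm_outer_radius * 2 > min(head_shape) * voxel_size) {
    config_error("gray-matter shell does not fit inside the head grid")
  }
  if (noise_cv < 0 || psf_fwhm < 0) {
    config_error("`noise_cv` and `psf_fwhm` must be >= 0")
  }
  structure(list(
    voxel_size = voxel_size, head_shape = head_shape,
    torso_slices = torso_slices, wm_radius = wm_radius,
    gm_outer_radius = gm_outer_radius,
    ventricle_offset_x = ventricle_offset_x,
    ventricle_semiaxes = ventricle_semiaxes,
    lesion_radius = lesion_radius, liver_semiaxes = liver_semiaxes,
    liver_offset_x = liver_offset_x, aorta_radius = aorta_radius,
    aorta_offset_x = aorta_offset_x, psf_fwhm = psf_fwhm,
    noise_cv = noise_cv
  ), class = "phantom_geometry")
}

#' Scoring tolerances
#'
#' Numeric conventions used when assigning visual scores from quantitative
#' SUVmax values. The IMS level 3 criterion ("similar to cerebral white
#' matter") is quantified as a symmetric relative band around the
#' white-matter SUVmax.
#'
#' @param ims3_band Half-width of the IMS 3 band as a fraction of the
#'   white-matter SUVmax; must satisfy `0 <= ims3_band < 0.5`.
#' @return A list of class `scoring_tolerances`.
#' @export
scoring_tolerances <- function(ims3_band = 0.10) {
  if (!is.numeric(ims3_band) || ims3_band < 0 || ims3_band >= 0.5) {
    config_error("`ims3_band` must satisfy 0 <= ims3_band < 0.5")
  }
  structure(list(ims3_band = ims3_band), class = "scoring_tolerances")
}

#' Covariate prevalences for the synthetic cohort
#'
#' Marginal distributions of the baseline covariates drawn by
#' [simulate_covariates()]. Defaults follow the baseline characteristics of
#' an end-of-therapy PET/CT PCNSL cohort: 53% male, median age in the late
#' fifties, half the patients with ECOG > 1, roughly a third each with
#' superficial / deep / both lesion sites, and 55% multifocal disease.
#'
#' @param p_male Probability of male sex.
#' @param age_mean,age_sd,age_range Normal age distribution (years), clamped
#'   to `age_range` and rounded to whole years.
#' @param p_ecog_gt1 Probability of ECOG performance status > 1.
#' @param p_ldh_elevated Probability of elevated serum LDH.
#' @param p_csf_protein_elevated Probability of elevated CSF protein.
#' @param p_site Named probabilities for lesion site
#'   `c(superficial, deep, both)`; deep involvement means site is deep or
#'   both.
#' @param p_multiple Probability of more than one lesion.
#' @return A list of class `cohort_prevalences`.
#' @export
cohort_prevalences <- function(p_male = 0.526,
                               age_mean = 56, age_sd = 13,
                               age_range = c(20, 85),
                               p_ecog_gt1 = 0.5,
                               p_ldh_elevated = 0.35,
                               p_csf_protein_elevated = 0.45,
                               p_site = c(superficial = 0.342,
                                          deep = 0.289, both = 0.369),
                               p_multiple = 0.553) {
  check_prob(p_male, "p_male")
  check_prob(p_ecog_gt1, "p_ecog_gt1")
  check_prob(p_ldh_elevated, "p_ldh_elevated")
  check_prob(p_csf_protein_elevated, "p_csf_protein_elevated")
  check_prob(p_multiple, "p_multiple")
  check_prob(p_site, "p_site")
  if (length(p_site) != 3 ||
      !setequal(names(p_site), c("superficial", "deep", "both"))) {
    config_error("`p_site` needs entries superficial, deep, both")
  }
  if (abs(sum(p_site) - 1) > 1e-6) {
    config_error("`p_site` probabilities must sum to 1")
  }
  structure(list(
    p_male = p_male, age_mean = age_mean, age_sd = age_sd,
    age_range = age_range, p_ecog_gt1 = p_ecog_gt1,
    p_ldh_elevated = p_ldh_elevated,
    p_csf_protein_elevated = p_csf_protein_elevated,
    p_site = p_site[c("superficial", "deep", "both")],
    p_multiple = p_multiple
  ), class = "cohort_prevalences")
}

#' Default IMS score distributions
#'
#' Five probabilities over IMS 1-5 matching the observed end-of-therapy
#' score distributions: 8/9/11/5/5 of 38 on PET/CT and 10/9/12/9/5 of 45 on
#' PET/MR.
#'
#' @param mode `"PET_CT"` or `"PET_MR"`.
#' @return Numeric vector of length 5 summing to 1.
#' @export
ims_score_distribution <- function(mode = c("PET_CT", "PET_MR")) {
  mode <- match.arg(mode)
  if (mode == "PET_CT") c(8, 9, 11, 5, 5) / 38 else c(10, 9, 12, 9, 5) / 45
}
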