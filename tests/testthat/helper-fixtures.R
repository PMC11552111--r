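# Shared fixtures: a small, fast phantom geometry and cohort builders.

test_geometry <- function(psf_fwhm = 0, noise_cv = 0) {
  phantom_geometry(
    voxel_size = 2.5, head_shape = c(48, 48, 48), torso_slices = 24,
    wm_radius = 34, gm_outer_radius = 50,
    ventricle_offset_x = 9, ventricle_semiaxes = c(6.5, 16, 6.5),
    lesion_radius = 5.5,
    liver_semiaxes = c(35, 28, 20), liver_offset_x = 18,
    aorta_radius = 11, aorta_offset_x = -22,
    psf_fwhm = psf_fwhm, noise_cv = noise_cv
  )
}

test_cohort <- function(n = 6, seed = 1, ...) {
  simulate_covariates(n, seed = seed, ...) |>
    compute_ielsg() |>
    compute_mskcc() |>
    simulate_true_scores(seed = seed) |>
    simulate_outcomes(seed = seed)
}

flat_panel <- function(gm = 9.45, wm = 2.81, csf = 1.50,
                       liver = 2.96, mediastinum = 1.80) {
  tibble::tibble(suv_gm = gm, suv_wm = wm, suv_csf = csf,
                 suv_liver = liver, suv_mediastinum = mediastinum)
}
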