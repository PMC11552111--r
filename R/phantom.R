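# Digital PET phantom: containers for activity volumes and label maps, and
# the per-patient phantom generator.

#' PET activity volume
#'
#' A 3D activity-concentration field (mCi/mL) with voxel geometry and the
#' acquisition metadata needed to convert activity to SUV.
#'
#' @param voxels 3D numeric array of nonnegative activity concentrations,
#'   mCi/mL.
#' @param voxel_size Voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param injected_dose Injected activity, mCi (> 0).
#' @param body_weight Body weight, g (> 0).
#' @param modality `"PET_CT"` or `"PET_MR"`.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(voxels, voxel_size, injected_dose, body_weight,
                       modality = c("PET_CT", "PET_MR")) {
  modality <- match.arg(modality)
  if (length(dim(voxels)) != 3) validation_error("`voxels` must be 3D")
  if (any(voxels < 0)) validation_error("negative activity values")
  if (!length(voxel_size) %in% c(1, 3) || any(voxel_size <= 0)) {
    validation_error("`voxel_size` must be 1 or 3 positive lengths (mm)")
  }
  if (!is.numeric(injected_dose) || injected_dose <= 0) {
    validation_error("`injected_dose` must be > 0")
  }
  if (!is.numeric(body_weight) || body_weight <= 0) {
    validation_error("`body_weight` must be > 0")
  }
  structure(list(voxels = voxels,
                 voxel_size = if (length(voxel_size) == 1)
                   rep(voxel_size, 3) else voxel_size,
                 injected_dose = injected_dose,
                 body_weight = body_weight, modality = modality),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(sprintf(
    "<pet_volume> %s  grid %s  voxel %s mm  dose %.3g mCi  weight %.4g g\n",
    x$modality, paste(dim(x$voxels), collapse = "x"),
    paste(signif(x$voxel_size, 3), collapse = "x"),
    x$injected_dose, x$body_weight))
  invisible(x)
}

#' Integer label map aligned to a PET volume
#'
#' @param voxels 3D integer array of structure labels.
#' @param labels Named integer vector mapping structure names (`background`,
#'   `GM`, `WM`, `CSF`, `liver`, `mediastinum`, `lesion_1`, ...) to label
#'   values.
#' @return An object of class `label_map`.
#' @export
label_map <- function(voxels, labels) {
  if (length(dim(voxels)) != 3) validation_error("`voxels` must be 3D")
  if (is.null(names(labels)) || anyNA(labels)) {
    validation_error("`labels` must be a named integer vector")
  }
  used <- setdiff(unique(as.integer(voxels)), labels)
  if (length(used)) {
    validation_error("label map contains values absent from `labels`")
  }
  structure(list(voxels = voxels, labels = setNames(as.integer(labels),
                                                    names(labels))),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> grid %s  structures: %s\n",
              paste(dim(x$voxels), collapse = "x"),
              toString(names(x$labels))))
  invisible(x)
}

lesion_label_names <- function(labels) {
  grep("^lesion_", names(labels$labels), value = TRUE)
}

#' Draw per-patient reference SUVmax panels
#'
#' Samples the SUVmax of each reference structure from its calibrated
#' truncated-normal distribution, with a common within-patient uptake
#' factor inducing correlation `rho` between structures. Panels whose CSF
#' value reaches 85% of the white-matter value are redrawn: such a panel
#' leaves no residual-uptake band between CSF and the white-matter
#' similarity band (0.90 of white matter at the default band width), and
#' the margin below 0.90 leaves headroom for measurement noise.
#' PET/MR panels omit the body references (liver, mediastinal blood pool).
#'
#' @param n Number of panels.
#' @param calibration A [reference_calibration()] object.
#' @param modality `"PET_CT"` or `"PET_MR"`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return Tibble with columns `suv_gm`, `suv_wm`, `suv_csf`, `suv_liver`,
#'   `suv_mediastinum` (the last two `NA` for PET/MR).
#' @examples
#' draw_reference_panel(3, seed = 1)
#' @export
draw_reference_panel <- function(n, calibration = reference_calibration(),
                                 modality = c("PET_CT", "PET_MR"),
                                 seed = NULL) {
  modality <- match.arg(modality)
  if (!inherits(calibration, "reference_calibration")) {
    config_error("`calibration` must come from reference_calibration()")
  }
  lower <- attr(calibration, "lower")
  rho <- attr(calibration, "rho") %||% 0
  draw_n <- function(m) {
    z_common <- rnorm(m)
    g <- function(s) {
      r <- calibration[calibration$structure == s, ]
      mu <- r$mean_suv + r$sd_suv * sqrt(rho) * z_common
      sdr <- r$sd_suv * sqrt(1 - rho)
      rtruncnorm_lower(m, mu, sdr, lower)
    }
    tibble(
      suv_gm = g("GM"), suv_wm = g("WM"), suv_csf = g("CSF"),
      suv_liver = if (modality == "PET_CT") g("liver") else NA_real_,
      suv_mediastinum = if (modality == "PET_CT") g("mediastinum")
                        else NA_real_
    )
  }
  draw <- function() {
    out <- draw_n(n)
    for (it in 1:100) {
      bad <- out$suv_csf >= 0.85 * out$suv_wm
      if (!any(bad)) break
      out[bad, ] <- draw_n(sum(bad))
    }
    if (any(out$suv_csf >= 0.85 * out$suv_wm)) {
      validation_error("could not draw a non-degenerate reference panel")
    }
    out
  }
  if (is.null(seed)) draw() else with_seed_local(seed, draw())
}

# ---- geometry rasterisation ------------------------------------------------

# mm coordinate arrays for a grid, origin at the grid centre.
coord_grids <- function(shape, voxel_size, z_range = NULL) {
  cc <- lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) *
                 voxel_size)
  list(
    x = array(rep(cc[[1]], times = shape[2] * shape[3]), shape),
    y = array(rep(rep(cc[[2]], each = shape[1]), times = shape[3]), shape),
    z = array(rep(cc[[3]], each = shape[1] * shape[2]), shape)
  )
}

in_sphere <- function(g, c0, r) {
  (g$x - c0[1])^2 + (g$y - c0[2])^2 + (g$z - c0[3])^2 <= r^2
}

in_ellipsoid <- function(g, c0, semi) {
  ((g$x - c0[1]) / semi[1])^2 + ((g$y - c0[2]) / semi[2])^2 +
    ((g$z - c0[3]) / semi[3])^2 <= 1
}

# Deterministic lesion centres inside the white-matter core, lateral to the
# ventricles, all in one hemisphere.
lesion_centers <- function(geometry, k, side) {
  if (k == 0) return(matrix(numeric(0), ncol = 3))
  lx <- side * (geometry$wm_radius + geometry$ventricle_offset_x +
                  geometry$ventricle_semiaxes[1]) / 2
  if (k == 1) return(cbind(lx, 0, 0))
  # ring in the y-z plane keeps lesions pairwise disjoint up to k = 4
  theta <- 2 * pi * (seq_len(k) - 1) / k
  rho <- 0.35 * geometry$wm_radius
  cbind(lx, rho * cos(theta), rho * sin(theta))
}

# Build the label map for one patient. Head occupies the top `head_shape[3]`
# slices; PET/CT appends a torso slab below with liver and descending aorta.
build_label_map <- function(geometry, modality, n_lesions = 0,
                            lesion_side = 1) {
  gm <- geometry
  torso <- if (modality == "PET_CT") gm$torso_slices else 0L
  shape <- c(gm$head_shape[1:2], gm$head_shape[3] + torso)
  h <- gm$voxel_size
  g <- coord_grids(shape, h)
  # head centre sits mid-way through the top head_shape[3] slices
  zc_head <- (torso / 2) * h
  gh <- list(x = g$x, y = g$y, z = g$z - zc_head)
  lab <- array(0L, shape)
  labels <- c(background = 0L, GM = 1L, WM = 2L, CSF = 3L)

  gm_mask <- in_sphere(gh, c(0, 0, 0), gm$gm_outer_radius)
  wm_mask <- in_sphere(gh, c(0, 0, 0), gm$wm_radius)
  lab[gm_mask] <- 1L
  lab[wm_mask] <- 2L
  for (s in c(-1, 1)) {
    vent <- in_ellipsoid(gh, c(s * gm$ventricle_offset_x, 0, 0),
                         gm$ventricle_semiaxes)
    if (any(vent & !wm_mask)) {
      geometry_error("ventricle extends outside the white-matter core")
    }
    lab[vent] <- 3L
  }
  if (n_lesions > 0) {
    ctr <- lesion_centers(gm, n_lesions, lesion_side)
    for (j in seq_len(n_lesions)) {
      les <- in_sphere(gh, ctr[j, ], gm$lesion_radius)
      if (any(les & lab != 2L)) {
        geometry_error(sprintf(
          "lesion_%d does not fit inside the white-matter region", j))
      }
      lv <- 10L + j
      lab[les] <- lv
      labels[sprintf("lesion_%d", j)] <- lv
    }
  }
  if (torso > 0) {
    zc_torso <- -(gm$head_shape[3] / 2) * h
    gt <- list(x = g$x, y = g$y, z = g$z - zc_torso)
    liver <- in_ellipsoid(gt, c(gm$liver_offset_x, 0, 0), gm$liver_semiaxes)
    lab[liver & lab == 0L] <- 4L
    aorta_len <- 0.8 * torso * h
    aorta <- (gt$x - gm$aorta_offset_x)^2 + gt$y^2 <= gm$aorta_radius^2 &
      abs(gt$z) <= aorta_len / 2
    lab[aorta & lab == 0L] <- 5L
    labels <- c(labels, liver = 4L, mediastinum = 5L)
  }
  label_map(lab, labels)
}

# Separable Gaussian blur via the FFT (periodic edges; the phantom border is
# zero-activity background so wrap-around is immaterial).
gaussian_blur3d <- function(a, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(a)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(a)
  tf <- lapply(1:3, function(ax) {
    n <- d[ax]
    f <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)[1:n] / (n * voxel_size)
    exp(-2 * pi^2 * sigma^2 * f^2)
  })
  tr <- outer(outer(tf[[1]], tf[[2]]), tf[[3]])
  Re(fft(fft(a) * tr, inverse = TRUE)) / prod(d)
}

# SUV band implied by a true IMS level, relative to a drawn panel. Draws
# uniformly from the central 60% of the band so blur/noise rarely push a
# lesion across a score boundary.
lesion_target_suv <- function(true_ims, panel, band) {
  lo_hi <- switch(as.character(true_ims),
    "2" = c(panel$suv_csf, (1 - band) * panel$suv_wm),
    "3" = c((1 - band) * panel$suv_wm, (1 + band) * panel$suv_wm),
    "4" = c((1 + band) * panel$suv_wm, panel$suv_gm),
    "5" = c(panel$suv_gm, 1.6 * panel$suv_gm),
    validation_error("lesions exist only for IMS 2-5"))
  runif(1, lo_hi[1] + 0.2 * diff(lo_hi), lo_hi[1] + 0.8 * diff(lo_hi))
}

#' Simulate a digital PET phantom for one patient
#'
#' Rasterises the analytic head (and, on PET/CT, torso) geometry, draws the
#' patient's reference SUVmax panel from the calibration, inserts lesion
#' spheres whose uptake lies in the SUV band implied by the patient's true
#' IMS relative to that panel, converts SUV targets to activity
#' (`activity = SUV * dose / weight`), then applies Gaussian point-spread
#' blur and multiplicative noise. With `psf_fwhm = 0` and `noise_cv = 0`
#' the plateau value inside each structure equals its target exactly.
#'
#' @param record One-row cohort tibble (needs `patient_id`, `true_ims`,
#'   `n_lesions`, `lesion_site`).
#' @param geometry A [phantom_geometry()] object.
#' @param calibration A [reference_calibration()] object.
#' @param dose Injected dose, mCi.
#' @param weight Body weight, g.
#' @param seed Master seed (patient substream `"phantom"`).
#' @param modality `"PET_CT"` (head + torso) or `"PET_MR"` (head only).
#' @param tol [scoring_tolerances()] defining the IMS 3 band used for
#'   lesion uptake bands.
#' @return A list with elements `volume` ([pet_volume]), `labels`
#'   ([label_map]) and `targets` (one-row tibble of the drawn reference and
#'   lesion SUVmax targets).
#' @examples
#' rec <- simulate_covariates(1, seed = 1) |> simulate_true_scores(seed = 1)
#' ph <- simulate_phantom(rec[1, ], phantom_geometry("compact"),
#'                        seed = 1, modality = "PET_MR")
#' @export
simulate_phantom <- function(record, geometry = phantom_geometry(),
                             calibration = reference_calibration(),
                             dose = 7, weight = 65000, seed = 1,
                             modality = c("PET_CT", "PET_MR"),
                             tol = scoring_tolerances()) {
  modality <- match.arg(modality)
  if (!inherits(geometry, "phantom_geometry")) {
    config_error("`geometry` must come from phantom_geometry()")
  }
  if (dose <= 0 || weight <= 0) {
    validation_error("`dose` and `weight` must be > 0")
  }
  if (nrow(record) != 1) validation_error("`record` must be a single row")
  ims <- record$true_ims
  if (is.na(ims)) missing_data_error("record needs `true_ims`")
  n_les <- if (ims == 1) 0L else max(1L, record$n_lesions)
  side <- if (isTRUE(record$lesion_site == "superficial")) -1 else 1

  labels <- build_label_map(geometry, modality, n_les, side)
  with_seed_local(substream_seed(seed, record$patient_id, "phantom"), {
    panel <- draw_reference_panel(1, calibration, modality)
    les_suv <- if (n_les > 0) {
      vapply(seq_len(n_les), function(j)
        lesion_target_suv(ims, panel, tol$ims3_band), numeric(1))
    } else numeric(0)
    suv_map <- c(0, panel$suv_gm, panel$suv_wm, panel$suv_csf,
                 if (modality == "PET_CT") c(panel$suv_liver,
                                             panel$suv_mediastinum)
                 else c(0, 0))
    lut_keys <- c(0:5, seq_len(n_les) + 10L)
    lut_vals <- c(suv_map, les_suv)
    suv_vol <- array(lut_vals[match(labels$voxels, lut_keys)],
                     dim(labels$voxels))
    act <- suv_vol * dose / weight
    # acquisition noise precedes the reconstruction point-spread smoothing
    if (geometry$noise_cv > 0) {
      act <- act * pmax(0, 1 + geometry$noise_cv * rnorm(length(act)))
    }
    act <- gaussian_blur3d(act, geometry$psf_fwhm, geometry$voxel_size)
    act <- pmax(act, 0)
    vol <- pet_volume(act, geometry$voxel_size, dose, weight, modality)
    targets <- dplyr::bind_cols(
      tibble(patient_id = record$patient_id, true_ims = as.integer(ims)),
      panel,
      tibble(suv_lesion_targets = list(les_suv))
    )
    list(volume = vol, labels = labels, targets = targets)
  })
}
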