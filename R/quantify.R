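# SUV conversion, rule-based reference ROI placement, and SUVmax extraction.

#' Convert an activity volume to SUV
#'
#' Standardized uptake value, elementwise:
#' `SUV = activity (mCi/mL) * body weight (g) / injected dose (mCi)`.
#'
#' @param volume A [pet_volume()].
#' @return 3D numeric array of SUV values, same shape as the input.
#' @examples
#' v <- pet_volume(array(0.001, c(4, 4, 4)), 2, injected_dose = 7,
#'                 body_weight = 70000)
#' suv_field(v)[1, 1, 1]  # 10
#' @export
suv_field <- function(volume) {
  if (!inherits(volume, "pet_volume")) {
    validation_error("`volume` must be a pet_volume")
  }
  volume$voxels * volume$body_weight / volume$injected_dose
}

# ---- Euclidean distance transform -----------------------------------------

# 1D squared distance transform (lower envelope of parabolas), with sample
# spacing `h`. `f` holds squared distances from previous passes; BIG stands
# in for +Inf.
BIG_DIST2 <- 1e12

sq_edt_1d <- function(f, h = 1) {
  n <- length(f)
  if (n == 1) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1)
  k <- 1L
  v[1] <- 1L
  z[1] <- -Inf
  z[2] <- Inf
  x <- seq_len(n) * h
  for (q in 2L:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + x[q]^2) - (f[vk] + x[vk]^2)) / (2 * (x[q] - x[vk]))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1L:n) {
    while (z[k + 1] < x[q]) k <- k + 1L
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

edt_pass <- function(a, axis, h) {
  d <- dim(a)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  b <- if (axis == 1) a else aperm(a, perm)
  m <- matrix(b, nrow = dim(b)[1])
  m <- apply(m, 2, sq_edt_1d, h = h)
  b <- array(m, dim(b))
  if (axis == 1) b else aperm(b, order(perm))
}

# Distance (mm) from each in-mask voxel centre to the nearest out-of-mask
# voxel centre; 0 outside the mask. Computed on the mask's bounding box.
distance_to_boundary <- function(mask, voxel_size) {
  d <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) return(array(0, d))
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  f <- array(ifelse(sub, BIG_DIST2, 0), dim(sub))
  # voxels touching the crop border but not the mask border: the crop pad
  # guarantees a non-mask voxel on every side unless the mask touches the
  # grid edge, where the edge itself is treated as boundary by padding.
  pad <- array(0, dim(sub) + 2L)
  pad[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), 2:(dim(sub)[3] + 1)] <- f
  for (ax in 1:3) pad <- edt_pass(pad, ax, voxel_size[min(ax, length(voxel_size))])
  f <- pad[2:(dim(sub)[1] + 1), 2:(dim(sub)[2] + 1), 2:(dim(sub)[3] + 1)]
  out <- array(0, d)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sqrt(f)
  out[!mask] <- 0
  out
}

# 6-neighbourhood binary erosion.
erode6 <- function(mask) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by == 1) { dst[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { dst[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  res <- mask
  for (ax in 1:3) for (by in c(1, -1)) res <- res & shift(mask, ax, by)
  res
}

#' Place a reference ROI inside a labelled structure
#'
#' Places a sphere (or, for the descending aorta, an axis-aligned cylinder
#' spanning contiguous slices) of the requested diameter at the structure's
#' deepest interior point -- the maximum of the Euclidean distance transform
#' inside the structure, ties broken towards the lowest linear voxel index.
#' The cylinder variant first erodes the structure by one voxel to exclude
#' wall voxels.
#'
#' @param labels A [label_map()].
#' @param structure Structure name present in the label dictionary.
#' @param diameter ROI diameter, mm.
#' @param voxel_size Voxel edge lengths, mm (length 1 or 3).
#' @param shape `"sphere"` or `"cylinder"` (cylinder height = diameter,
#'   axis along z).
#' @param within Optional logical array further restricting the allowed
#'   region (e.g. one hemisphere).
#' @return Integer vector of linear voxel indices in the ROI; attribute
#'   `center` holds the chosen centre (voxel indices).
#' @export
place_roi <- function(labels, structure, diameter, voxel_size,
                      shape = c("sphere", "cylinder"), within = NULL) {
  shape <- match.arg(shape)
  if (!inherits(labels, "label_map")) {
    validation_error("`labels` must be a label_map")
  }
  if (!structure %in% names(labels$labels)) {
    placement_error(sprintf("structure '%s' absent from label map",
                            structure))
  }
  vs <- if (length(voxel_size) == 1) rep(voxel_size, 3) else voxel_size
  mask <- labels$voxels == labels$labels[[structure]]
  if (!is.null(within)) mask <- mask & within
  if (!any(mask)) {
    placement_error(sprintf("structure '%s' absent from label map",
                            structure))
  }
  roi_mask <- mask
  if (shape == "cylinder") roi_mask <- erode6(mask)
  if (!any(roi_mask)) {
    placement_error(sprintf(
      "structure '%s' too small after wall exclusion", structure))
  }
  dist <- distance_to_boundary(roi_mask, vs)
  r <- diameter / 2
  maxd <- max(dist)
  if (maxd < r) {
    placement_error(sprintf(
      "structure '%s' too small for a %.3g mm ROI (max depth %.3g mm)",
      structure, diameter, maxd))
  }
  ci <- arrayInd(which.max(dist), dim(dist))  # first max = lowest index
  d <- dim(roi_mask)
  idx <- which(roi_mask)
  ai <- arrayInd(idx, d)
  dx <- (ai[, 1] - ci[1]) * vs[1]
  dy <- (ai[, 2] - ci[2]) * vs[2]
  dz <- (ai[, 3] - ci[3]) * vs[3]
  keep <- if (shape == "sphere") {
    dx^2 + dy^2 + dz^2 <= r^2
  } else {
    dx^2 + dy^2 <= r^2 & abs(dz) <= r
  }
  out <- idx[keep]
  attr(out, "center") <- as.integer(ci)
  out
}

roi_diameters <- function() {
  c(GM = 10, WM = 10, CSF = 10, liver = 30, mediastinum = 15)
}

#' Measure the reference SUVmax panel for one scan
#'
#' Applies the reference ROI rules: >= 1 cm spheres for gray matter, white
#' matter and the ventricular CSF; a 3 cm sphere in the liver; a 1.5 cm
#' cylinder on the descending aorta with wall voxels excluded. Gray- and
#' white-matter ROIs are placed in the hemisphere contralateral to the
#' uptake-weighted lesion centroid (either hemisphere when no lesion is
#' present). PET/MR scans yield no liver or mediastinum entry.
#'
#' @param volume A [pet_volume()].
#' @param labels The aligned [label_map()].
#' @return One-row tibble: `suv_gm`, `suv_wm`, `suv_csf`, `suv_liver`,
#'   `suv_mediastinum` (body references `NA` for PET/MR).
#' @export
measure_reference_panel <- function(volume, labels) {
  if (!identical(dim(volume$voxels), dim(labels$voxels))) {
    validation_error("volume and label map grids differ")
  }
  suv <- suv_field(volume)
  vs <- volume$voxel_size
  dia <- roi_diameters()
  need <- c("GM", "WM", "CSF")
  miss <- setdiff(need, names(labels$labels))
  if (length(miss)) {
    validation_error(paste("missing required structures:", toString(miss)))
  }
  d <- dim(labels$voxels)
  # contralateral hemisphere restriction for GM/WM
  les_names <- lesion_label_names(labels)
  hemi <- NULL
  if (length(les_names)) {
    les_mask <- labels$voxels %in% labels$labels[les_names]
    if (any(les_mask)) {
      w <- volume$voxels[les_mask]
      if (all(w <= 0)) w <- rep(1, length(w))
      cx <- sum(arrayInd(which(les_mask), d)[, 1] * w) / sum(w)
      mid <- (d[1] + 1) / 2
      xs <- slice.index(labels$voxels, 1)
      hemi <- if (cx < mid) xs > mid else xs < mid
    }
  }
  suvmax_of <- function(structure, shape = "sphere", within = NULL) {
    roi <- place_roi(labels, structure, dia[[structure]], vs,
                     shape = shape, within = within)
    max(suv[roi])
  }
  out <- tibble(
    suv_gm = suvmax_of("GM", within = hemi),
    suv_wm = suvmax_of("WM", within = hemi),
    suv_csf = suvmax_of("CSF"),
    suv_liver = NA_real_, suv_mediastinum = NA_real_
  )
  if (volume$modality == "PET_CT") {
    miss <- setdiff(c("liver", "mediastinum"), names(labels$labels))
    if (length(miss)) {
      validation_error(paste("missing required structures:",
                             toString(miss)))
    }
    out$suv_liver <- suvmax_of("liver")
    out$suv_mediastinum <- suvmax_of("mediastinum", shape = "cylinder")
  }
  out
}

#' Measure lesion SUVmax values
#'
#' One row per lesion label: SUVmax over all the lesion's voxels and the
#' lesion volume in mL. Returns an empty tibble when the label map carries
#' no lesions.
#'
#' @param volume A [pet_volume()].
#' @param labels The aligned [label_map()].
#' @return Tibble with columns `lesion_id`, `suvmax`, `volume_ml`.
#' @export
measure_lesions <- function(volume, labels) {
  if (!identical(dim(volume$voxels), dim(labels$voxels))) {
    validation_error("volume and label map grids differ")
  }
  les_names <- lesion_label_names(labels)
  if (!length(les_names)) {
    return(tibble(lesion_id = character(0), suvmax = numeric(0),
                  volume_ml = numeric(0)))
  }
  suv <- suv_field(volume)
  vox_ml <- prod(volume$voxel_size) / 1000
  purrr::map_dfr(les_names, function(nm) {
    m <- labels$voxels == labels$labels[[nm]]
    tibble(lesion_id = nm,
           suvmax = if (any(m)) max(suv[m]) else NA_real_,
           volume_ml = sum(m) * vox_ml)
  })
}

#' Quantify one scan into a cohort row
#'
#' Combines [measure_reference_panel()] and [measure_lesions()] into the
#' per-patient quantification record consumed by [score_cohort()].
#'
#' @param volume A [pet_volume()].
#' @param labels The aligned [label_map()].
#' @return One-row tibble: reference panel columns, `suv_lesion_max`
#'   (`NA` when no lesions) and `n_lesions`.
#' @export
quantify_scan <- function(volume, labels) {
  panel <- measure_reference_panel(volume, labels)
  les <- measure_lesions(volume, labels)
  dplyr::mutate(panel,
                suv_lesion_max = if (nrow(les)) max(les$suvmax) else NA_real_,
                n_lesions = nrow(les),
                modality = volume$modality)
}
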