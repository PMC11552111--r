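# SUV conversion, ROI placement, reference panel and lesion measurement.

make_sphere_map <- function(shape = c(40, 40, 40), voxel = 2,
                            center = NULL, radius = 30, label = 4L,
                            name = "liver") {
  if (is.null(center)) center <- (shape + 1) / 2
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  vox <- array(ifelse(d2 * voxel^2 <= radius^2, label, 0L), shape)
  label_map(vox, setNames(c(0L, label), c("background", name)))
}

test_that("suv_field applies the SUV formula elementwise", {
  v <- pet_volume(array(0.001, c(3, 3, 3)), 2, injected_dose = 7,
                  body_weight = 70000)
  expect_equal(suv_field(v)[2, 2, 2], 10.0)

  v0 <- pet_volume(array(0, c(3, 3, 3)), 2, 7, 70000)
  expect_true(all(suv_field(v0) == 0))

  v2 <- pet_volume(array(5e-4, c(2, 2, 2)), 2, injected_dose = 5,
                   body_weight = 60000)
  expect_equal(suv_field(v2)[1, 1, 1], 6.0)

  expect_error(pet_volume(array(1, c(2, 2, 2)), 2, 0, 70000),
               class = "imscore_validation_error")
  expect_error(pet_volume(array(1, c(2, 2, 2)), 2, 7, -1),
               class = "imscore_validation_error")
  expect_error(pet_volume(array(-1, c(2, 2, 2)), 2, 7, 70000),
               class = "imscore_validation_error")
})

test_that("SUVmax scales exactly with activity", {
  co <- test_cohort(8, seed = 12)
  rec <- co[which(co$true_ims > 1)[1], ]
  ph <- simulate_phantom(rec, test_geometry(), seed = 12)
  q1 <- quantify_scan(ph$volume, ph$labels)
  v2 <- ph$volume
  v2$voxels <- v2$voxels * 3
  q2 <- quantify_scan(v2, ph$labels)
  for (col in c("suv_gm", "suv_wm", "suv_csf", "suv_liver",
                "suv_mediastinum", "suv_lesion_max")) {
    expect_equal(q2[[col]], 3 * q1[[col]], tolerance = 1e-12)
  }
})

test_that("spherical ROI lands at the deepest point of a sphere", {
  lm <- make_sphere_map(radius = 30)   # 6 cm sphere, 2 mm voxels
  roi <- place_roi(lm, "liver", diameter = 30, voxel_size = 2)
  expect_equal(attr(roi, "center"), as.integer(c(20, 20, 20)) + 0L)
  # containment: every ROI voxel carries the structure label
  expect_true(all(lm$voxels[roi] == lm$labels[["liver"]]))

  expect_error(place_roi(lm, "spleen", 30, 2),
               class = "imscore_placement_error")
  small <- make_sphere_map(radius = 10)
  expect_error(place_roi(small, "liver", diameter = 30, voxel_size = 2),
               class = "imscore_placement_error")
})

test_that("discretised sphere ROI volume matches brute-force enumeration", {
  # 1 cm sphere, 2 mm voxels, inside an ellipsoid
  shape <- c(30, 30, 30)
  g <- expand.grid(i = 1:30, j = 1:30, k = 1:30)
  inside <- ((g$i - 15.5) / 12)^2 + ((g$j - 15.5) / 9)^2 +
    ((g$k - 15.5) / 7)^2 <= 1
  lm <- label_map(array(ifelse(inside, 1L, 0L), shape),
                  c(background = 0L, GM = 1L))
  roi <- place_roi(lm, "GM", diameter = 10, voxel_size = 2)
  # oracle: voxel centres within 5 mm of the chosen centre
  ctr <- attr(roi, "center")
  d2 <- (g$i - ctr[1])^2 + (g$j - ctr[2])^2 + (g$k - ctr[3])^2
  oracle <- sum(d2 * 4 <= 25 & inside)
  expect_equal(length(roi), oracle)
  # continuum volume (4/3) pi 5^3 / 8 ~ 65 voxels; discretisation keeps
  # the count in the right regime
  expect_gt(length(roi), 40)
  expect_lt(length(roi), 110)
})

test_that("aorta cylinder excludes wall voxels by erosion", {
  shape <- c(30, 30, 40)
  g <- expand.grid(i = 1:30, j = 1:30, k = 1:40)
  inside <- (g$i - 15.5)^2 + (g$j - 15.5)^2 <= (12 / 2)^2 & g$k >= 5 &
    g$k <= 36
  lm <- label_map(array(ifelse(inside, 5L, 0L), shape),
                  c(background = 0L, mediastinum = 5L))
  roi <- place_roi(lm, "mediastinum", diameter = 15, voxel_size = 2,
                   shape = "cylinder")
  ai <- arrayInd(as.integer(roi), shape)
  # all ROI voxels inside the structure, none on its wall
  expect_true(all(lm$voxels[roi] == 5L))
  wall_r <- sqrt((ai[, 1] - 15.5)^2 + (ai[, 2] - 15.5)^2)
  expect_true(max(wall_r) < 6 - 1)   # at least one voxel off the wall
  # contiguous slices
  expect_true(all(diff(sort(unique(ai[, 3]))) == 1))
})

test_that("GM/WM ROIs are placed contralateral to the lesion", {
  co <- test_cohort(20, seed = 13)
  rec <- co[which(co$true_ims > 1)[1], ]
  ph <- simulate_phantom(rec, test_geometry(), seed = 13,
                         modality = "PET_MR")
  d <- dim(ph$labels$voxels)
  les_labels <- ph$labels$labels[grepl("^lesion_",
                                       names(ph$labels$labels))]
  les_mask <- ph$labels$voxels %in% les_labels
  les_x <- mean(arrayInd(which(les_mask), d)[, 1])
  mid <- (d[1] + 1) / 2

  suv <- suv_field(ph$volume)
  # recompute the GM ROI with the exported placement routine
  hemi <- if (les_x < mid) slice.index(ph$labels$voxels, 1) > mid else
    slice.index(ph$labels$voxels, 1) < mid
  roi <- place_roi(ph$labels, "GM", 10, ph$volume$voxel_size,
                   within = hemi)
  ctr <- attr(roi, "center")
  expect_true((les_x < mid) == (ctr[1] > mid))
  # and the panel's GM value comes from that hemisphere
  pan <- measure_reference_panel(ph$volume, ph$labels)
  expect_equal(pan$suv_gm, max(suv[roi]), tolerance = 1e-12)
})

test_that("measure_lesions returns one row per lesion and empty when none", {
  co <- test_cohort(20, seed = 14)
  rec <- co[which(co$n_lesions >= 2)[1], ]
  ph <- simulate_phantom(rec, test_geometry(), seed = 14,
                         modality = "PET_MR")
  les <- measure_lesions(ph$volume, ph$labels)
  expect_equal(nrow(les), rec$n_lesions)
  expect_equal(max(les$suvmax), max(ph$targets$suv_lesion_targets[[1]]),
               tolerance = 1e-12)
  expect_true(all(les$volume_ml > 0))

  rec1 <- co[which(co$true_ims == 1)[1], ]
  ph1 <- simulate_phantom(rec1, test_geometry(), seed = 14,
                          modality = "PET_MR")
  expect_equal(nrow(measure_lesions(ph1$volume, ph1$labels)), 0)
})

test_that("PET_MR panels never contain body references", {
  co <- test_cohort(8, seed = 16)
  ph <- simulate_phantom(co[1, ], test_geometry(), seed = 16,
                         modality = "PET_MR")
  pan <- measure_reference_panel(ph$volume, ph$labels)
  expect_true(is.na(pan$suv_liver))
  expect_true(is.na(pan$suv_mediastinum))
  expect_gt(pan$suv_gm, 0)
})
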