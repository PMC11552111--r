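# Synthetic cohort generator: contracts, prognostic indices, outcome model.

test_that("simulate_covariates enforces its contract and invariants", {
  expect_error(simulate_covariates(0), class = "imscore_config_error")
  expect_error(cohort_prevalences(p_male = 1.2),
               class = "imscore_config_error")

  co <- simulate_covariates(38, seed = 1)
  expect_equal(nrow(co), 38)
  expect_true(all(co$ecog %in% 0:4))
  expect_true(all(co$kps %% 10 == 0 & co$kps >= 0 & co$kps <= 100))
  expect_true(all(co$age >= 20 & co$age <= 85))
  expect_true(all(co$lesion_site %in% c("superficial", "deep", "both")))
  expect_identical(co$deep_lesion, co$lesion_site %in% c("deep", "both"))
  expect_true(all(co$n_lesions >= 1))
})

test_that("covariate marginals match configured prevalences at large n", {
  co <- simulate_covariates(10000, cohort_prevalences(p_male = 0.53),
                            seed = 42)
  # binomial SE at n = 10000 is 0.005; allow 3 SE
  expect_lt(abs(mean(co$sex == "male") - 0.53), 0.015)
})

test_that("cohort generation is deterministic and substream-stable", {
  a <- test_cohort(10, seed = 9)
  b <- test_cohort(10, seed = 9)
  expect_identical(a, b)
  # enlarging the cohort must not reshuffle existing patients
  big <- test_cohort(20, seed = 9)
  expect_identical(a, big[1:10, ])
})

test_that("IELSG counts the five adverse factors and folds 4-5 upward", {
  d <- tibble::tibble(
    age = c(65, 40, 61), ecog = c(2L, 1L, 0L),
    ldh_elevated = c(TRUE, FALSE, FALSE),
    csf_protein_elevated = c(TRUE, FALSE, FALSE),
    deep_lesion = c(TRUE, FALSE, TRUE)
  )
  r <- compute_ielsg(d)
  expect_equal(r$ielsg_score, c(5L, 0L, 2L))
  expect_equal(r$ielsg_group, c("2-3", "0-1", "2-3"))
  expect_error(compute_ielsg(dplyr::select(d, -ecog)),
               class = "imscore_missing_data_error")
  d$age[1] <- NA
  expect_error(compute_ielsg(d), class = "imscore_missing_data_error")
})

test_that("MSKCC maps to the three recursive-partitioning classes", {
  d <- tibble::tibble(age = c(45, 60, 60), kps = c(60, 90, 60))
  expect_equal(compute_mskcc(d)$mskcc_class, c(0L, 1L, 2L))
  d$kps[2] <- NA
  expect_error(compute_mskcc(d), class = "imscore_missing_data_error")
})

test_that("true score assignment follows the configured distribution", {
  co <- simulate_covariates(200, seed = 3)
  all1 <- simulate_true_scores(co, c(1, 0, 0, 0, 0), seed = 3)
  expect_true(all(all1$true_ims == 1L))
  expect_true(all(all1$n_lesions == 0L))
  expect_true(all(!all1$new_lesion_flag))

  expect_error(simulate_true_scores(co, c(0.5, 0.5), seed = 3),
               class = "imscore_config_error")
  expect_error(simulate_true_scores(co, c(-0.1, 0.3, 0.3, 0.3, 0.2),
                                    seed = 3),
               class = "imscore_config_error")

  big <- simulate_covariates(10000, seed = 5) |>
    simulate_true_scores(ims_score_distribution("PET_CT"), seed = 5)
  p <- ims_score_distribution("PET_CT")
  se <- sqrt(p * (1 - p) / 10000)
  frac <- as.numeric(table(factor(big$true_ims, 1:5))) / 10000
  expect_true(all(abs(frac - p) < 3 * se))
  # lesion count invariant: zero lesions iff IMS 1
  expect_identical(big$n_lesions == 0L,
                   big$true_ims == 1L & !big$new_lesion_flag)
})

test_that("outcome model keeps endpoint coherence", {
  co <- test_cohort(300, seed = 11)
  expect_true(all(co$os_time >= co$pfs_time))
  expect_true(all(co$pfs_time > 0))
  # death implies progression-or-death event
  expect_true(all(!co$os_event | co$pfs_event))
  # non-progressors are censored identically on both endpoints
  idx <- !co$pfs_event
  expect_equal(co$os_time[idx], co$pfs_time[idx])
  expect_true(all(!co$os_event[idx]))
  expect_true(all(co$pfs_time <= hazard_config()$admin_horizon))
})

test_that("extreme censoring censors everyone", {
  co <- simulate_covariates(50, seed = 2) |>
    simulate_true_scores(seed = 2) |>
    simulate_outcomes(hazard_config(censor_rate = 1000), seed = 2)
  expect_true(all(!co$pfs_event))
  expect_true(all(!co$os_event))
  expect_error(hazard_config(baseline_hazard = -1),
               class = "imscore_config_error")
})

test_that("Cox recovers the configured IMS 4-5 hazard ratio at n = 2000", {
  co <- simulate_covariates(2000, seed = 21) |>
    simulate_true_scores(seed = 21) |>
    simulate_outcomes(hazard_config(censor_rate = 0,
                                    admin_horizon = 1e7), seed = 21)
  d <- dplyr::mutate(co, hi = as.integer(true_ims >= 4))
  fit <- tidy(cox_fit(d, pfs_time, pfs_event, "hi"))
  # +/- 2 asymptotic SE around HR 9.04 at this size
  expect_gt(fit$hr, 7.0)
  expect_lt(fit$hr, 11.7)
})

test_that("second reader keeps or shifts scores by one level", {
  expect_identical(simulate_second_reader(integer(0)), integer(0))
  s <- rep(1:5, 40)
  expect_identical(simulate_second_reader(s, agreement = 1, seed = 1), s)
  expect_equal(cohen_kappa(s, simulate_second_reader(s, 1, 1)), 1)

  r2 <- simulate_second_reader(s, agreement = 0.5, seed = 2)
  expect_true(all(abs(r2 - s) <= 1))
  expect_true(all(r2 %in% 1:5))

  big <- rep(rep(1:5, c(8, 9, 11, 5, 5)), length.out = 10000)
  k <- cohen_kappa(big, simulate_second_reader(big, 0.95, seed = 3))
  expect_gt(k, 0.85)
  expect_lt(k, 0.99)
})
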