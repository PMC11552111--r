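# Synthetic cohort generation: covariates, prognostic indices, true scores,
# proportional-hazards outcomes, and a second simulated reader.
#
# Every patient owns a random substream derived by hashing their id with the
# master seed, so regenerating a larger cohort leaves existing patients'
# draws untouched.

#' Simulate baseline covariates for a synthetic PCNSL cohort
#'
#' Draws one row per patient with demographics, performance status,
#' laboratory flags, and lesion-site descriptors. Outcome fields
#' (`true_ims`, survival times) are left unset; see
#' [simulate_true_scores()] and [simulate_outcomes()].
#'
#' @param n Number of patients (>= 1).
#' @param prevalences A [cohort_prevalences()] object.
#' @param seed Master integer seed; each patient's draws come from a
#'   substream hashed from this seed and the patient id.
#' @param cohort Cohort label, `"PET_CT"` or `"PET_MR"`.
#' @return A tibble with one row per patient: `patient_id`, `cohort`, `age`,
#'   `sex`, `ecog`, `kps`, `ldh_elevated`, `csf_protein_elevated`,
#'   `lesion_site`, `deep_lesion`, `n_lesions`, plus `true_ims`,
#'   `new_lesion_flag`, `pfs_time`, `pfs_event`, `os_time`, `os_event`
#'   initialised to missing.
#' @examples
#' simulate_covariates(5, seed = 1)
#' @export
simulate_covariates <- function(n, prevalences = cohort_prevalences(),
                                seed = 1,
                                cohort = c("PET_CT", "PET_MR")) {
  cohort <- match.arg(cohort)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    config_error("`n` must be a positive integer")
  }
  if (!inherits(prevalences, "cohort_prevalences")) {
    config_error("`prevalences` must come from cohort_prevalences()")
  }
  p <- prevalences
  ids <- sprintf("P%04d", seq_len(n))
  site_levels <- c("superficial", "deep", "both")
  draws <- vapply(ids, function(id) {
    with_seed_local(substream_seed(seed, id, "covariates"), {
      age <- round(min(max(rnorm(1, p$age_mean, p$age_sd),
                           p$age_range[1]), p$age_range[2]))
      male <- runif(1) < p$p_male
      ecog <- if (runif(1) < p$p_ecog_gt1) sample(2:3, 1) else sample(0:1, 1)
      # KPS tracks ECOG downward in 10-point steps with individual spread
      kps <- 100 - 10 * ecog - 10 * rbinom(1, 2, 0.3)
      ldh <- runif(1) < p$p_ldh_elevated
      csf <- runif(1) < p$p_csf_protein_elevated
      site <- sample(3L, 1, prob = p$p_site[site_levels])
      nles <- if (runif(1) < p$p_multiple) sample(2:4, 1) else 1L
      c(age, male, ecog, kps, ldh, csf, site, nles)
    })
  }, numeric(8))
  dimnames(draws) <- NULL
  site <- site_levels[draws[7, ]]
  tibble(
    patient_id = ids, cohort = cohort, age = unname(draws[1, ]),
    sex = ifelse(draws[2, ] > 0, "male", "female"),
    ecog = as.integer(draws[3, ]), kps = as.integer(draws[4, ]),
    ldh_elevated = draws[5, ] > 0, csf_protein_elevated = draws[6, ] > 0,
    lesion_site = site, deep_lesion = site %in% c("deep", "both"),
    n_lesions = as.integer(draws[8, ]),
    true_ims = NA_integer_, new_lesion_flag = NA,
    pfs_time = NA_real_, pfs_event = NA,
    os_time = NA_real_, os_event = NA
  )
}

#' IELSG prognostic score
#'
#' Counts the five adverse factors of the International Extranodal Lymphoma
#' Study Group index -- age > 60 years, ECOG > 1, elevated LDH, elevated CSF
#' protein, and deep brain lesions -- and folds the 0-5 count into the
#' conventional low ("0-1") and high ("2-3") risk groups (counts of 4-5 fold
#' into the high group).
#'
#' @param data Cohort tibble with columns `age`, `ecog`, `ldh_elevated`,
#'   `csf_protein_elevated`, `deep_lesion`.
#' @return `data` with columns `ielsg_score` (integer 0-5) and
#'   `ielsg_group` (`"0-1"` / `"2-3"`) added. Missing covariates raise a
#'   missing-data error rather than being imputed.
#' @examples
#' simulate_covariates(3, seed = 1) |> compute_ielsg()
#' @export
compute_ielsg <- function(data) {
  need <- c("age", "ecog", "ldh_elevated", "csf_protein_elevated",
            "deep_lesion")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    missing_data_error(paste("missing columns:", toString(miss)))
  }
  if (anyNA(data[need])) {
    missing_data_error("IELSG covariates contain missing values")
  }
  dplyr::mutate(
    data,
    ielsg_score = as.integer(
      (.data$age > 60) + (.data$ecog > 1) + .data$ldh_elevated +
        .data$csf_protein_elevated + .data$deep_lesion),
    ielsg_group = ifelse(.data$ielsg_score <= 1, "0-1", "2-3")
  )
}

#' MSKCC prognostic class
#'
#' Three-class Memorial Sloan-Kettering Cancer Center index from the
#' recursive-partitioning split on age and Karnofsky performance status:
#' class 0 if age <= 50; class 1 if age > 50 and KPS >= 70; class 2 if
#' age > 50 and KPS < 70.
#'
#' @param data Cohort tibble with columns `age` and `kps`.
#' @return `data` with an integer `mskcc_class` column added.
#' @examples
#' tibble::tibble(age = c(45, 60, 60), kps = c(60, 90, 60)) |>
#'   compute_mskcc()
#' @export
compute_mskcc <- function(data) {
  miss <- setdiff(c("age", "kps"), names(data))
  if (length(miss)) {
    missing_data_error(paste("missing columns:", toString(miss)))
  }
  if (anyNA(data[c("age", "kps")])) {
    missing_data_error("MSKCC covariates contain missing values")
  }
  dplyr::mutate(data, mskcc_class = as.integer(
    ifelse(.data$age <= 50, 0L, ifelse(.data$kps >= 70, 1L, 2L))))
}

#' Assign true IMS categories to a simulated cohort
#'
#' Draws each patient's underlying response category (IMS 1-5) from a
#' configurable distribution. Patients assigned IMS 1 (no residual uptake)
#' get `n_lesions = 0` and no new-lesion flag; a minority of IMS 5 patients
#' carry the new-lesion flag.
#'
#' @param data Cohort tibble from [simulate_covariates()].
#' @param distribution Five probabilities over IMS 1-5 summing to 1; see
#'   [ims_score_distribution()].
#' @param seed Master seed (per-patient substreams).
#' @param p_new_lesion_given_ims5 Probability that an IMS 5 patient is
#'   scored 5 because of a new lesion.
#' @return `data` with `true_ims`, `new_lesion_flag` and `n_lesions`
#'   updated.
#' @examples
#' simulate_covariates(5, seed = 1) |> simulate_true_scores(seed = 1)
#' @export
simulate_true_scores <- function(data,
                                 distribution = ims_score_distribution("PET_CT"),
                                 seed = 1,
                                 p_new_lesion_given_ims5 = 0.3) {
  if (length(distribution) != 5 || !is.numeric(distribution)) {
    config_error("`distribution` must be 5 probabilities over IMS 1-5")
  }
  if (any(distribution < 0)) {
    config_error("`distribution` has a negative probability")
  }
  if (abs(sum(distribution) - 1) > 1e-9) {
    config_error("`distribution` must sum to 1")
  }
  check_prob(p_new_lesion_given_ims5, "p_new_lesion_given_ims5")
  draws <- vapply(data$patient_id, function(id) {
    with_seed_local(substream_seed(seed, id, "true_ims"), {
      s <- sample.int(5, 1, prob = distribution)
      nl <- s == 5 && runif(1) < p_new_lesion_given_ims5
      c(s, nl)
    })
  }, numeric(2))
  data |>
    dplyr::mutate(
      true_ims = as.integer(unname(draws[1, ])),
      new_lesion_flag = unname(draws[2, ]) > 0,
      n_lesions = as.integer(ifelse(.data$true_ims == 1L, 0L,
                                    pmax(.data$n_lesions, 1L)))
    )
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Progression-free survival is exponential with hazard
#' `baseline_hazard * exp(log_hr_ims45 * 1[IMS >= 4] + log_hr_ims5_extra *
#' 1[IMS = 5])`, censored by independent exponential dropout truncated at
#' the administrative horizon. Overall survival equals the progression time
#' plus an exponential post-progression survival draw for progressors
#' (administratively censored at the horizon), and equals the censoring time
#' for non-progressors, so `os_time >= pfs_time` always holds.
#'
#' @param data Cohort tibble with `true_ims` set.
#' @param hazard A [hazard_config()] object.
#' @param seed Master seed (per-patient substreams).
#' @return `data` with `pfs_time`, `pfs_event`, `os_time`, `os_event`
#'   filled in (days, event indicators logical).
#' @examples
#' simulate_covariates(5, seed = 1) |>
#'   simulate_true_scores(seed = 1) |>
#'   simulate_outcomes(seed = 1)
#' @export
simulate_outcomes <- function(data, hazard = hazard_config(), seed = 1) {
  if (!inherits(hazard, "hazard_config")) {
    config_error("`hazard` must come from hazard_config()")
  }
  if (anyNA(data$true_ims)) {
    missing_data_error("`true_ims` must be set before simulating outcomes")
  }
  h <- hazard
  draws <- vapply(seq_len(nrow(data)), function(i) {
    id <- data$patient_id[i]
    ims <- data$true_ims[i]
    lhr <- h$log_hr_ims45 * (ims >= 4) + h$log_hr_ims5_extra * (ims == 5)
    with_seed_local(substream_seed(seed, id, "outcomes"), {
      t_prog <- rexp(1, h$baseline_hazard * exp(lhr))
      cens <- if (h$censor_rate > 0) {
        min(rexp(1, h$censor_rate), h$admin_horizon)
      } else h$admin_horizon
      if (t_prog <= cens) {
        pfs_time <- t_prog; pfs_event <- TRUE
        death <- t_prog + rexp(1, h$post_progression_hazard)
        if (death <= h$admin_horizon) c(pfs_time, 1, death, 1)
        else c(pfs_time, 1, h$admin_horizon, 0)
      } else {
        c(cens, 0, cens, 0)
      }
    })
  }, numeric(4))
  data |>
    dplyr::mutate(
      pfs_time = pmax(draws[1, ], 1e-6),
      pfs_event = draws[2, ] > 0,
      os_time = pmax(draws[3, ], 1e-6),
      os_event = draws[4, ] > 0
    )
}

#' Simulate an independent second reader
#'
#' Emulates blinded double reading of the scans: each score is kept with
#' probability `agreement` and otherwise shifted one level up or down
#' (clamped to 1-5).
#'
#' @param scores Integer vector of scores in 1-5.
#' @param agreement Probability of agreeing with the first reader.
#' @param seed Integer seed.
#' @return Integer vector of the same length.
#' @examples
#' simulate_second_reader(c(1L, 3L, 5L), agreement = 0.9, seed = 1)
#' @export
simulate_second_reader <- function(scores, agreement = 0.95, seed = 1) {
  check_prob(agreement, "agreement")
  if (!length(scores)) return(integer(0))
  if (any(!scores %in% 1:5)) validation_error("scores must be in 1-5")
  with_seed_local(seed, {
    keep <- runif(length(scores)) < agreement
    shift <- ifelse(scores == 1L, 1L,
                    ifelse(scores == 5L, -1L,
                           sample(c(-1L, 1L), length(scores), replace = TRUE)))
    as.integer(ifelse(keep, scores, scores + shift))
  })
}
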