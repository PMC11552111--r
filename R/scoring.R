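# IMS and Deauville score assignment, grouping schemes, inter-rater kappa.

check_panel_value <- function(panel, what) {
  v <- panel[[what]]
  if (is.null(v) || length(v) != 1 || is.na(v) || v <= 0) {
    validation_error(sprintf("reference panel lacks a positive `%s`", what))
  }
  v
}

#' Assign the intracranial metabolic score (IMS)
#'
#' Five-level score of residual lesion uptake against the intracranial
#' references, from the hottest lesion SUVmax `L`:
#' \itemize{
#'   \item 5 -- new lesion present, or `L >` gray matter;
#'   \item 4 -- `L >` white matter (beyond the similarity band) and
#'     `L <=` gray matter;
#'   \item 3 -- `L` within the similarity band around white matter
#'     (`(1 - band) * WM <= L <= (1 + band) * WM`);
#'   \item 2 -- `L >` CSF and below the white-matter band;
#'   \item 1 -- no residual lesion, or `L <=` CSF.
#' }
#' Boundary ties resolve to the lower score (the score definitions use
#' strict "greater than"). The patient-level score uses the maximum lesion
#' SUVmax.
#'
#' @param lesion_suvmax Numeric vector of lesion SUVmax values (may be
#'   empty / length 0 for no residual lesion).
#' @param panel One-row reference panel (needs positive `suv_gm`, `suv_wm`,
#'   `suv_csf`); a degenerate panel with `suv_csf >= (1 - band) * suv_wm`
#'   is rejected because the bands would no longer partition the line.
#' @param new_lesion Logical; a new lesion forces score 5.
#' @param tol A [scoring_tolerances()] object.
#' @return Integer score 1-5.
#' @examples
#' p <- tibble::tibble(suv_gm = 9.45, suv_wm = 2.81, suv_csf = 1.50)
#' assign_ims(2.0, p)   # 2
#' assign_ims(12, p)    # 5
#' @export
assign_ims <- function(lesion_suvmax, panel, new_lesion = FALSE,
                       tol = scoring_tolerances()) {
  gm <- check_panel_value(panel, "suv_gm")
  wm <- check_panel_value(panel, "suv_wm")
  csf <- check_panel_value(panel, "suv_csf")
  band <- tol$ims3_band
  if (csf >= (1 - band) * wm) {
    validation_error(
      "degenerate panel: CSF SUVmax reaches the white-matter band")
  }
  if (isTRUE(new_lesion)) return(5L)
  lesion_suvmax <- lesion_suvmax[!is.na(lesion_suvmax)]
  if (!length(lesion_suvmax)) return(1L)
  L <- max(lesion_suvmax)
  if (L < 0) validation_error("lesion SUVmax must be >= 0")
  if (L > gm) 5L
  else if (L > (1 + band) * wm) 4L
  else if (L >= (1 - band) * wm) 3L
  else if (L > csf) 2L
  else 1L
}

#' Assign the Deauville 5-point score (DS)
#'
#' Standard lymphoma response scale against the mediastinal blood pool and
#' liver, from the hottest lesion SUVmax `L`: 5 if a new lesion is present
#' or `L > 2 * liver`; 4 if `liver < L <= 2 * liver`; 3 if
#' `mediastinum < L <= liver`; 2 if a lesion is present with
#' `L <= mediastinum`; 1 if no residual lesion. The scale is inapplicable
#' to PET/MR panels, which lack both body references.
#'
#' @inheritParams assign_ims
#' @param panel One-row reference panel with positive `suv_liver` and
#'   `suv_mediastinum`; otherwise a `imscore_ds_inapplicable` error is
#'   raised.
#' @return Integer score 1-5.
#' @examples
#' p <- tibble::tibble(suv_liver = 2.96, suv_mediastinum = 1.80)
#' assign_ds(6.5, p)  # 5: above twice the liver
#' @export
assign_ds <- function(lesion_suvmax, panel, new_lesion = FALSE) {
  lv <- panel[["suv_liver"]]
  mb <- panel[["suv_mediastinum"]]
  if (is.null(lv) || is.null(mb) || length(lv) != 1 || length(mb) != 1 ||
      is.na(lv) || is.na(mb)) {
    abort(paste("DS inapplicable: panel lacks the mediastinal blood pool",
                "and/or liver reference"),
          class = c("imscore_ds_inapplicable", "imscore_validation_error"))
  }
  if (lv <= 0 || mb <= 0) {
    validation_error("liver and mediastinum SUVmax must be > 0")
  }
  if (isTRUE(new_lesion)) return(5L)
  lesion_suvmax <- lesion_suvmax[!is.na(lesion_suvmax)]
  if (!length(lesion_suvmax)) return(1L)
  L <- max(lesion_suvmax)
  if (L < 0) validation_error("lesion SUVmax must be >= 0")
  if (L > 2 * lv) 5L
  else if (L > lv) 4L
  else if (L > mb) 3L
  else if (L > 0) 2L
  else 1L
}

#' Group 5-level scores into the published stratifications
#'
#' @param score Integer vector of scores in 1-5.
#' @param scheme One of `"five"` (each level its own group),
#'   `"1-3_vs_4-5"`, `"1-4_vs_5"`, or `"1-2_3-4_5"` (three groups).
#' @return Factor of group labels (`"1-3"`/`"4-5"`, `"1-4"`/`"5"`,
#'   `"1-2"`/`"3-4"`/`"5"`, or `"1"`..`"5"`).
#' @examples
#' group_scores(c(1, 4, 5), "1-3_vs_4-5")
#' @export
group_scores <- function(score,
                         scheme = c("five", "1-3_vs_4-5", "1-4_vs_5",
                                    "1-2_3-4_5")) {
  if (any(!score %in% 1:5)) validation_error("scores must be in 1-5")
  scheme <- tryCatch(match.arg(scheme),
                     error = function(e) config_error("unknown scheme"))
  switch(scheme,
    "five" = factor(as.character(score), levels = as.character(1:5)),
    "1-3_vs_4-5" = factor(ifelse(score <= 3, "1-3", "4-5"),
                          levels = c("1-3", "4-5")),
    "1-4_vs_5" = factor(ifelse(score <= 4, "1-4", "5"),
                        levels = c("1-4", "5")),
    "1-2_3-4_5" = factor(ifelse(score <= 2, "1-2",
                                ifelse(score <= 4, "3-4", "5")),
                         levels = c("1-2", "3-4", "5"))
  )
}

#' Unweighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters on the same subjects:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and
#' chance agreement `p_e` from the raters' marginal distributions. When both
#' raters are constant and identical (`p_e = 1`, `p_o = 1`) kappa is defined
#' as 1.
#'
#' @param ratings_a,ratings_b Equal-length vectors of categorical ratings.
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(c(1, 2, 1, 2), c(1, 2, 2, 2))  # 0.5
#' @export
cohen_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b)) {
    validation_error("rating vectors differ in length")
  }
  if (!length(ratings_a)) validation_error("need at least one rating")
  cats <- sort(unique(c(ratings_a, ratings_b)))
  pa <- table(factor(ratings_a, cats)) / length(ratings_a)
  pb <- table(factor(ratings_b, cats)) / length(ratings_b)
  p_o <- mean(ratings_a == ratings_b)
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (1 - p_e < 1e-12) {
    if (p_o >= 1 - 1e-12) return(1) else return(0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Score a quantified cohort
#'
#' Adds IMS (and, where the body references exist, DS) columns to a cohort
#' tibble of quantified SUVmax values, plus group labels for each published
#' stratification scheme.
#'
#' @param data Tibble with columns `suv_gm`, `suv_wm`, `suv_csf`,
#'   `suv_lesion_max` (NA for no lesion), `new_lesion_flag`, and optionally
#'   `suv_liver` / `suv_mediastinum` (NA on PET/MR rows, where DS is
#'   recorded as NA).
#' @param tol A [scoring_tolerances()] object.
#' @return `data` with columns `ims`, `ds`, `ims_group_45`, `ims_group_5`,
#'   `ims_group_3way` added.
#' @export
score_cohort <- function(data, tol = scoring_tolerances()) {
  need <- c("suv_gm", "suv_wm", "suv_csf", "suv_lesion_max")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    missing_data_error(paste("missing columns:", toString(miss)))
  }
  nl <- if ("new_lesion_flag" %in% names(data)) {
    !is.na(data$new_lesion_flag) & data$new_lesion_flag
  } else rep(FALSE, nrow(data))
  ims <- vapply(seq_len(nrow(data)), function(i) {
    assign_ims(data$suv_lesion_max[i], data[i, ], nl[i], tol)
  }, integer(1))
  ds <- vapply(seq_len(nrow(data)), function(i) {
    row <- data[i, ]
    if (is.null(row[["suv_liver"]]) || is.na(row[["suv_liver"]]) ||
        is.null(row[["suv_mediastinum"]]) ||
        is.na(row[["suv_mediastinum"]])) {
      return(NA_integer_)
    }
    assign_ds(data$suv_lesion_max[i], row, nl[i])
  }, integer(1))
  data |>
    dplyr::mutate(
      ims = ims, ds = ds,
      ims_group_45 = group_scores(ims, "1-3_vs_4-5"),
      ims_group_5 = group_scores(ims, "1-4_vs_5"),
      ims_group_3way = group_scores(ims, "1-2_3-4_5")
    )
}
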