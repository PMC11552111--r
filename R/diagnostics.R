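# Diagnostic test metrics, contingency reconstruction from published
# marginals, and ordinal ROC AUC.

#' Diagnostic metrics from a 2x2 contingency table
#'
#' Sensitivity, specificity, positive and negative predictive value (as
#' percentages) and the two-point trapezoidal AUC
#' `(sensitivity + specificity) / 2` (as a fraction) from true/false
#' positive/negative counts. A metric whose denominator is zero is returned
#' as `NA` (undefined), never as 0.
#'
#' @param tp,fp,fn,tn Nonnegative integer counts (scalars or equal-length
#'   vectors); alternatively pass a data frame with these columns as `tp`.
#' @return Tibble with columns `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv` (percent) and `auc` (fraction).
#' @examples
#' diagnostic_metrics(8, 2, 4, 24)
#' @export
diagnostic_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.data.frame(tp)) {
    d <- tp
    miss <- setdiff(c("tp", "fp", "fn", "tn"), names(d))
    if (length(miss)) {
      validation_error(paste("missing columns:", toString(miss)))
    }
    tp <- d$tp; fp <- d$fp; fn <- d$fn; tn <- d$tn
  }
  cells <- cbind(tp, fp, fn, tn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    validation_error("counts must be nonnegative integers")
  }
  if (any(rowSums(cells) <= 0)) {
    validation_error("table total must be positive")
  }
  ratio <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = sens, specificity = spec,
    ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
    auc = (sens + spec) / 200
  )
}

#' Reconstruct a 2x2 table from published marginals and one anchor metric
#'
#' Inverts a published diagnostic table: given the cohort size, the number
#' of events, the number of score-positive patients, and one printed metric
#' (sensitivity or PPV, in percent), the integer table is uniquely
#' determined: `tp` is the anchor-implied count rounded to the nearest
#' integer, `fp = positives - tp`, `fn = events - tp`,
#' `tn = n - tp - fp - fn`. Reconstruction fails if any cell is negative or
#' the resulting table does not reproduce the anchor to the printed
#' precision.
#'
#' @param n Cohort size.
#' @param events Number of patients with the outcome event.
#' @param positives Number of score-positive patients.
#' @param anchor Named length-1 numeric: `c(sensitivity = ...)` or
#'   `c(ppv = ...)`, in percent as printed.
#' @param tol_pct Maximum absolute disagreement (percentage points) between
#'   the printed anchor and the anchor recomputed from the integer table.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`.
#' @examples
#' reconstruct_contingency(38, 12, 10, c(sensitivity = 66.7))
#' @export
reconstruct_contingency <- function(n, events, positives, anchor,
                                    tol_pct = 0.05) {
  if (length(anchor) != 1 || is.null(names(anchor)) ||
      !names(anchor) %in% c("sensitivity", "ppv")) {
    config_error("`anchor` must be c(sensitivity = x) or c(ppv = x)")
  }
  if (events < 0 || events > n || positives < 0 || positives > n) {
    reconstruction_error(
      "inconsistent marginals: events/positives outside 0..n")
  }
  tp <- if (names(anchor) == "sensitivity") {
    round(anchor[[1]] / 100 * events)
  } else {
    round(anchor[[1]] / 100 * positives)
  }
  fp <- positives - tp
  fn <- events - tp
  tn <- n - tp - fp - fn
  if (any(c(tp, fp, fn, tn) < 0)) {
    reconstruction_error("inconsistent marginals: negative cell implied")
  }
  back <- if (names(anchor) == "sensitivity") {
    if (events > 0) 100 * tp / events else NA_real_
  } else {
    if (positives > 0) 100 * tp / positives else NA_real_
  }
  if (is.na(back) || abs(round(back, 1) - anchor[[1]]) > tol_pct) {
    reconstruction_error(sprintf(
      "reconstructed table does not reproduce the %s anchor (%.2f vs %.2f)",
      names(anchor), back, anchor[[1]]))
  }
  tibble(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Ordinal ROC AUC for a 5-level score
#'
#' Trapezoidal area under the ROC curve over the ordinal thresholds --
#' equivalently the tie-corrected two-sample rank statistic
#' `P(score_case > score_control) + 0.5 P(equal)` -- with the Hanley-McNeil
#' asymptotic 95% confidence interval.
#'
#' @param scores Integer scores (e.g. IMS 1-5).
#' @param outcomes Logical outcome indicator; both classes must be present.
#' @return Tibble with `auc`, `conf.low`, `conf.high`, `n_pos`, `n_neg`.
#' @examples
#' ordinal_roc_auc(c(1, 2, 4, 5), c(FALSE, FALSE, TRUE, TRUE))
#' @export
ordinal_roc_auc <- function(scores, outcomes) {
  outcomes <- as.logical(outcomes)
  if (length(scores) != length(outcomes) || anyNA(scores) ||
      anyNA(outcomes)) {
    validation_error("scores and outcomes must align with no missing values")
  }
  n1 <- sum(outcomes)
  n0 <- sum(!outcomes)
  if (n1 == 0 || n0 == 0) {
    validation_error("both outcome classes must be present")
  }
  r <- rank(scores)
  auc <- (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n0 - 1) * (q2 - auc^2)) / (n1 * n0)
  z <- qnorm(0.975)
  half <- z * sqrt(max(v, 0))
  tibble(auc = auc,
         conf.low = max(0, auc - half), conf.high = min(1, auc + half),
         n_pos = n1, n_neg = n0)
}
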