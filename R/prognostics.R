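# Survival machinery: endpoint derivation, Kaplan-Meier, log-rank, Cox PH.
# Model fitting is delegated to the survival package; the wrappers add the
# validation, tidy output and error contracts the pipeline relies on.

#' Derive PFS and OS endpoints from dates
#'
#' Progression-free survival runs from treatment start to the first of
#' progression or death (event) or last follow-up (censored); overall
#' survival runs to death (event) or last follow-up (censored).
#'
#' @param treatment_start,last_followup `Date` vectors (recycled to common
#'   length); `last_followup >= treatment_start`.
#' @param progression_date,death_date `Date` vectors, `NA` where the event
#'   did not occur.
#' @return Tibble with `pfs_time`, `pfs_event`, `os_time`, `os_event`
#'   (times in days).
#' @examples
#' compute_endpoints(as.Date("2020-01-01"),
#'                   progression_date = as.Date("2020-04-10"),
#'                   death_date = as.Date(NA),
#'                   last_followup = as.Date("2021-02-04"))
#' @export
compute_endpoints <- function(treatment_start, progression_date = as.Date(NA),
                              death_date = as.Date(NA), last_followup) {
  n <- max(length(treatment_start), length(progression_date),
           length(death_date), length(last_followup))
  rec <- function(x) rep_len(x, n)
  start <- rec(treatment_start); prog <- rec(progression_date)
  death <- rec(death_date); fup <- rec(last_followup)
  if (any(fup < start)) data_error("last follow-up precedes treatment start")
  bad <- (!is.na(prog) & prog < start) | (!is.na(death) & death < start)
  if (any(bad)) {
    data_error("progression or death recorded before treatment start")
  }
  startn <- as.numeric(start)
  progn <- as.numeric(prog)
  deathn <- as.numeric(death)
  fupn <- as.numeric(fup)
  pfs_daten <- pmin(progn, deathn, na.rm = TRUE)
  pfs_event <- !is.na(pfs_daten)
  pfs_time <- ifelse(pfs_event, pfs_daten, fupn) - startn
  os_event <- !is.na(deathn)
  os_time <- ifelse(os_event, deathn, fupn) - startn
  if (any(pfs_time <= 0 | os_time <= 0)) {
    data_error("derived survival times must be positive")
  }
  tibble(pfs_time = pfs_time, pfs_event = pfs_event,
         os_time = os_time, os_event = os_event)
}

check_survival_input <- function(time, event) {
  if (any(is.na(time)) || any(time <= 0)) {
    validation_error("survival times must be positive")
  }
  if (length(time) != length(event)) {
    validation_error("`time` and `event` differ in length")
  }
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function, overall or by group,
#' with the median defined as the smallest time at which the estimated
#' survival drops to 0.5 or below (`NA` when the curve stays above 0.5).
#'
#' @param data Data frame of survival records.
#' @param time,event,group Column names (unquoted) of the time (days),
#'   event indicator, and optional grouping variable.
#' @return Object of class `ims_km`; use [tidy()] for the step function and
#'   [glance()] for per-group summaries (n, events, median).
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3), e = c(TRUE, TRUE, TRUE))
#' tidy(km_estimate(d, t, e))
#' @export
km_estimate <- function(data, time, event, group = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  check_survival_input(t, e)
  gq <- rlang::enquo(group)
  g <- if (rlang::quo_is_null(gq)) factor(rep("all", length(t)))
       else factor(dplyr::pull(data, !!gq))
  fit <- survival::survfit(survival::Surv(t, e) ~ g)
  strata <- if (is.null(fit$strata)) {
    rep(levels(g)[1], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  tbl <- tibble(
    group = strata, time = fit$time, n_risk = fit$n.risk,
    n_event = fit$n.event, n_censor = fit$n.censor, survival = fit$surv
  )
  med <- tbl |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = NA_integer_, events = sum(.data$n_event),
      median = if (any(.data$survival <= 0.5 + 1e-12))
        min(.data$time[.data$survival <= 0.5 + 1e-12]) else NA_real_,
      .groups = "drop")
  med$n <- as.integer(table(g)[med$group])
  structure(list(fit = fit, table = tbl, summary = med),
            class = "ims_km")
}

#' @export
print.ims_km <- function(x, ...) {
  cat("<ims_km> Kaplan-Meier estimate\n")
  print(x$summary)
  invisible(x)
}

#' @rdname km_estimate
#' @param x An `ims_km` object.
#' @param ... Unused.
#' @export
tidy.ims_km <- function(x, ...) x$table

#' @rdname km_estimate
#' @export
glance.ims_km <- function(x, ...) x$summary

#' Log-rank test
#'
#' Standard (unweighted) log-rank test comparing the survival of k >= 2
#' groups over the pooled event times.
#'
#' @inheritParams km_estimate
#' @param group Grouping column (required, >= 2 nonempty groups).
#' @return Tibble with `statistic` (chi-square), `df` (k - 1), `p.value`.
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3, 4), e = TRUE, g = c("a", "a", "b", "b"))
#' logrank_test(d, t, e, g)
#' @export
logrank_test <- function(data, time, event, group) {
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  check_survival_input(t, e)
  if (nlevels(g) < 2) {
    validation_error("log-rank test needs at least two nonempty groups")
  }
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  df <- nlevels(g) - 1
  tibble(statistic = sd$chisq, df = df,
         p.value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Maximises the Cox partial likelihood for the given covariates (Breslow
#' tie handling by default, Efron available) and reports the hazard ratio
#' with Wald 95% confidence interval and p-value per term. Monotone
#' likelihoods (e.g. all events confined to one group) are flagged as
#' non-converged with a diagnostic rather than reported as finite hazard
#' ratios.
#'
#' @inheritParams km_estimate
#' @param covariates Character vector of covariate column names.
#' @param ties `"breslow"` or `"efron"`.
#' @return Object of class `ims_cox`; [tidy()] gives per-term estimates
#'   (`term`, `estimate` = log HR, `std.error`, `hr`, `conf.low`,
#'   `conf.high` on the HR scale, `p.value`), [glance()] gives fit-level
#'   summaries.
#' @examples
#' d <- tibble::tibble(t = c(1, 2, 3, 4, 5, 6), e = TRUE,
#'                     x = c(1, 1, 1, 0, 0, 0))
#' tidy(cox_fit(d, t, e, "x"))
#' @export
cox_fit <- function(data, time, event, covariates,
                    ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  t <- dplyr::pull(data, {{ time }})
  e <- as.logical(dplyr::pull(data, {{ event }}))
  check_survival_input(t, e)
  if (sum(e) < 1) validation_error("Cox fit needs at least one event")
  miss <- setdiff(covariates, names(data))
  if (length(miss)) {
    missing_data_error(paste("missing covariates:", toString(miss)))
  }
  for (cv in covariates) {
    if (dplyr::n_distinct(data[[cv]]) < 2) {
      validation_error(sprintf("covariate `%s` is constant", cv))
    }
  }
  df <- data.frame(.time = t, .event = e,
                   data[covariates], check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  warn_monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w))) {
        warn_monotone <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- stats::coef(fit)
  if (anyNA(co)) {
    validation_error(
      "singular information matrix: collinear or duplicated covariates")
  }
  se <- sqrt(diag(fit$var))
  monotone <- warn_monotone | (abs(co) > 15) | (se > 1e3)
  z <- qnorm(0.975)
  tbl <- tibble(
    term = names(co), estimate = unname(co), std.error = unname(se),
    hr = exp(unname(co)),
    conf.low = exp(unname(co) - z * unname(se)),
    conf.high = exp(unname(co) + z * unname(se)),
    p.value = 2 * stats::pnorm(-abs(unname(co) / unname(se))),
    converged = !monotone
  )
  if (any(monotone)) {
    tbl$note <- ifelse(monotone,
                       "not available: monotone likelihood (limited events in one group)",
                       NA_character_)
  }
  structure(list(fit = fit, table = tbl, ties = ties,
                 n = fit$n, nevent = fit$nevent,
                 converged = !any(monotone)),
            class = "ims_cox")
}

#' @export
print.ims_cox <- function(x, ...) {
  cat(sprintf("<ims_cox> n = %d, events = %d, ties = %s%s\n", x$n,
              x$nevent, x$ties,
              if (!x$converged) "  [monotone likelihood flagged]" else ""))
  print(x$table)
  invisible(x)
}

#' @rdname cox_fit
#' @param x An `ims_cox` object.
#' @param ... Unused.
#' @export
tidy.ims_cox <- function(x, ...) x$table

#' @rdname cox_fit
#' @export
glance.ims_cox <- function(x, ...) {
  tibble(n = x$n, nevent = x$nevent, ties = x$ties,
         logLik = as.numeric(x$fit$loglik[2]), converged = x$converged)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square by default (continuity correction
#' available via `correct = TRUE`), two-sided p from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of nonnegative counts with positive marginals.
#' @param correct Apply the Yates continuity correction.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @examples
#' chi_square_2x2(matrix(c(20, 14, 18, 31), 2))
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!identical(dim(table), c(2L, 2L))) {
    validation_error("`table` must be 2x2")
  }
  if (any(table < 0) || sum(table) <= 0) {
    validation_error("counts must be nonnegative with a positive total")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    validation_error("zero marginal: chi-square test undefined")
  }
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = unname(ct$p.value))
}
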