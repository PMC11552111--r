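# ggplot2 visualisations for the result objects.

#' @describeIn km_estimate Step-function plot of the Kaplan-Meier curves.
#' @param object An `ims_km` object.
#' @export
autoplot.ims_km <- function(object, ...) {
  tbl <- object$table |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble(time = 0, survival = 1), .x[c("time", "survival")])) |>
    dplyr::ungroup()
  ggplot2::ggplot(tbl, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = "Group") +
    ggplot2::theme_minimal()
}

#' @describeIn cox_fit Forest plot of hazard ratios with Wald 95% CIs.
#' @param object An `ims_cox` object.
#' @export
autoplot.ims_cox <- function(object, ...) {
  tbl <- object$table
  ggplot2::ggplot(tbl, ggplot2::aes(.data$hr, .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of a cohort's score distribution
#'
#' @param data Scored cohort tibble with an `ims` (and optionally `ds`)
#'   column.
#' @param scale `"ims"` or `"ds"`.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(data, scale = c("ims", "ds")) {
  scale <- match.arg(scale)
  if (!scale %in% names(data)) {
    validation_error(sprintf("column `%s` not found", scale))
  }
  d <- tibble(score = factor(data[[scale]], levels = 1:5))
  ggplot2::ggplot(d[!is.na(data[[scale]]), , drop = FALSE],
                  ggplot2::aes(.data$score)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = toupper(scale), y = "Patients") +
    ggplot2::theme_minimal()
}
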