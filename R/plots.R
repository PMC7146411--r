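#' Box plots of forecast skill across sites
#'
#' One box per accumulation horizon (or lead) and method, summarising the
#' spread of a skill index over sites -- the standard way of reporting how
#' ETc forecast quality degrades with horizon.
#'
#' @param skill Skill tibble from [run_synthetic_experiment()] or
#'   [skill_scores()], with a `method` column and either `horizon` or
#'   `lead`.
#' @param value Index to plot: `"rmse"` (default) or `"bias"`.
#' @return A ggplot object.
#' @export
plot_skill <- function(skill, value = "rmse") {
  xcol <- if ("horizon" %in% names(skill)) "horizon" else "lead"
  ggplot2::ggplot(skill, ggplot2::aes(
    x = factor(.data[[xcol]]), y = .data[[value]], fill = .data$method
  )) +
    ggplot2::geom_boxplot(outlier.shape = 1, position = "dodge") +
    ggplot2::labs(
      x = if (xcol == "horizon") "Accumulation horizon (days)" else "Lead time (days)",
      y = if (value == "rmse") "RMSE (mm)" else "BIAS (mm)",
      fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Canopy season plot
#'
#' LAI and albedo through the season for each field, as a faceted line plot
#' with one point per satellite acquisition.
#'
#' @param canopy Canopy tibble (`field_id, date, lai, albedo`).
#' @return A ggplot object.
#' @export
plot_canopy <- function(canopy) {
  long <- canopy %>%
    select(all_of(c("field_id", "date", "lai", "albedo"))) %>%
    tidyr::pivot_longer(c("lai", "albedo"), names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$date, .data$value,
                                     colour = .data$field_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~parameter, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(lai = "LAI (m2/m2)", albedo = "albedo (-)"))) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Hargreaves-Samani calibration
#'
#' Fitted scaling factor per site with the calibration RMSE mapped to point
#' size, against the uncalibrated baseline k = 1.
#'
#' @param object A `khs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot khs_fit
#' @export
autoplot.khs_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$site_id, .data$k_hs,
                                  size = .data$rmse_cal_mm)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression(k[HS]),
                  size = "calibration RMSE (mm/day)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
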