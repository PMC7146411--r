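#' Forecast skill: BIAS and RMSE against the best estimate
#'
#' BIAS (mean forecast-minus-observed difference, an accuracy measure) and
#' RMSE (accuracy plus precision) over paired days,
#' \deqn{BIAS = \frac{1}{n}\sum_i (X_{f,i} - X_{obs,i}), \quad
#'   RMSE = \sqrt{\frac{1}{n}\sum_i (X_{f,i} - X_{obs,i})^2}.}
#' For evapotranspiration forecasts the comparison target is the one-step
#' Penman-Monteith value from observed weather (the "best estimate"). Pairs
#' with a missing value on either side are dropped.
#'
#' @param data A paired tibble (e.g. a join of forecasts and best estimates).
#' @param forecast,observed Column names (strings) of the two series.
#' @param by Character vector of grouping columns (e.g.
#'   `c("site_id", "lead")` or `c("site_id", "horizon")`); empty for a
#'   single overall score.
#' @return A tibble with the grouping columns plus `bias`, `rmse`, `n`.
#' @examples
#' d <- tibble::tibble(f = c(1, 3), o = c(2, 2))
#' skill_scores(d, "f", "o") # bias 0, rmse 1
#' @export
skill_scores <- function(data, forecast, observed, by = character()) {
  d <- as_tibble(data) %>%
    filter(is.finite(.data[[forecast]]), is.finite(.data[[observed]]))
  if (nrow(d) == 0) abort("No valid forecast/observation pairs.")
  d %>%
    group_by(across(all_of(by))) %>%
    summarise(
      bias = mean(.data[[forecast]] - .data[[observed]]),
      rmse = sqrt(mean((.data[[forecast]] - .data[[observed]])^2)),
      n = n(),
      .groups = "drop"
    )
}

#' Summarise a skill index across sites (box-plot statistics)
#'
#' Quartiles (linear interpolation between order statistics), mean and Tukey
#' whiskers of one skill index over a collection of sites: whiskers reach the
#' most extreme values inside the fences `p25 - 1.5 IQR` / `p75 + 1.5 IQR`;
#' values beyond them are listed as outliers.
#'
#' @param records Tibble of per-site skill records.
#' @param value Column name (string) of the index to summarise.
#' @return A one-row tibble: `p25, p50, p75, mean, whisker_lo, whisker_hi,
#'   n_outliers`, plus `outliers` (list column).
#' @export
summarize_over_sites <- function(records, value = "rmse") {
  v <- records[[value]]
  v <- v[is.finite(v)]
  if (length(v) == 0) abort("No records to summarise.")
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- v[v >= lo_fence & v <= hi_fence]
  tibble(
    p25 = q[1], p50 = q[2], p75 = q[3],
    mean = mean(v),
    whisker_lo = min(inside),
    whisker_hi = max(inside),
    n_outliers = sum(v < lo_fence | v > hi_fence),
    outliers = list(sort(v[v < lo_fence | v > hi_fence]))
  )
}
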