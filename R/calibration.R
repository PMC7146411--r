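#' Calibrate the Hargreaves-Samani scaling factor locally
#'
#' Fits the site-specific scaling factor by minimising the summed squared
#' differences between Hargreaves-Samani and Penman-Monteith reference ET
#' over a calibration period. Because the factor enters multiplicatively,
#' the minimiser has the closed form of least squares through the origin,
#' \deqn{k_{HS} = \sum_i h_i p_i / \sum_i h_i^2}
#' where `h` is the Hargreaves-Samani series evaluated at unit scaling and
#' `p` the Penman-Monteith series.
#'
#' @param data Paired daily tibble with columns `et0_hs_unit` (HS at
#'   `k_hs = 1`) and `et0_pm`, plus optionally `site_id` (fit per site) and
#'   `date`.
#' @param min_days Minimum paired days per site (default 30).
#' @return An object of class `khs_fit`. [generics::tidy()] returns one row
#'   per site (`site_id, k_hs, rmse_cal_mm, rmse_unit_mm, n_days, period`);
#'   [generics::glance()] a one-row overall summary.
#' @examples
#' d <- tibble::tibble(et0_hs_unit = 1:40 / 4, et0_pm = 0.5 * (1:40 / 4))
#' tidy(calibrate_khs(d))$k_hs # 0.5
#' @export
calibrate_khs <- function(data, min_days = 30) {
  required <- c("et0_hs_unit", "et0_pm")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  d <- as_tibble(data)
  if (!"site_id" %in% names(d)) d$site_id <- "site"
  d <- filter(d, is.finite(.data$et0_hs_unit), is.finite(.data$et0_pm))
  fits <- d %>%
    group_by(.data$site_id) %>%
    summarise(
      n_days = n(),
      sum_h2 = sum(.data$et0_hs_unit^2),
      k_hs = sum(.data$et0_hs_unit * .data$et0_pm) / .data$sum_h2,
      rmse_cal_mm = sqrt(mean((.data$k_hs * .data$et0_hs_unit - .data$et0_pm)^2)),
      rmse_unit_mm = sqrt(mean((.data$et0_hs_unit - .data$et0_pm)^2)),
      period = if ("date" %in% names(d)) {
        paste(format(range(.data$date)), collapse = "/")
      } else {
        NA_character_
      },
      .groups = "drop"
    )
  if (any(fits$sum_h2 == 0)) {
    abort("All-zero Hargreaves-Samani series: the scaling factor is unidentifiable.")
  }
  if (any(fits$n_days < min_days)) {
    abort(sprintf("Fewer than %d paired days at some site(s).", min_days))
  }
  structure(
    list(fits = select(fits, -all_of("sum_h2")), min_days = min_days),
    class = "khs_fit"
  )
}

#' @export
print.khs_fit <- function(x, ...) {
  cat(sprintf("<khs_fit> Hargreaves-Samani scaling factors at %d site(s)\n",
              nrow(x$fits)))
  print(x$fits, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname calibrate_khs
#' @param x A `khs_fit` object.
#' @param ... Unused.
#' @method tidy khs_fit
#' @export
tidy.khs_fit <- function(x, ...) {
  x$fits
}

#' @rdname calibrate_khs
#' @method glance khs_fit
#' @export
glance.khs_fit <- function(x, ...) {
  tibble(
    n_sites = nrow(x$fits),
    k_hs_mean = mean(x$fits$k_hs),
    k_hs_min = min(x$fits$k_hs),
    k_hs_max = max(x$fits$k_hs),
    rmse_cal_mean_mm = mean(x$fits$rmse_cal_mm)
  )
}

#' Write the fitted scaling factors to JSON
#'
#' One object per site: `site_id, k_hs, rmse_cal_mm, n_days, period`.
#'
#' @param fit A `khs_fit`.
#' @param path Output file.
#' @export
write_khs <- function(fit, path) {
  stopifnot(inherits(fit, "khs_fit"))
  jsonlite::write_json(fit$fits, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
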