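#' Analytic crop coefficient from the one-step approach
#'
#' The crop coefficient is the ratio of the one-step crop evapotranspiration
#' to the reference evapotranspiration, both from the Penman-Monteith
#' equation driven by the same observed weather:
#' \deqn{K_c = ET_{c\mathrm{-PM,obs}} / ET_{0\mathrm{-PM,obs}}}
#' Canopy parameters are those of the most recent satellite acquisition
#' (held constant between passes); weather is updated daily, so Kc carries
#' both a canopy and a weather signal.
#'
#' @inheritParams etc_penman_monteith
#' @param min_et0 Reference-ET floor, mm day^-1, below which Kc is undefined.
#' @param on_undefined `"error"` (default) or `"drop"` days whose reference
#'   ET falls below the floor.
#' @return A tibble `site_id, date, kc, canopy_date, etc_mm, et0_mm` (plus
#'   `field_id` if the canopy series carries one).
#' @export
crop_coefficient <- function(weather, canopy, sites, h_c = 0.4, min_et0 = 0.1,
                             on_undefined = c("error", "drop")) {
  on_undefined <- arg_match(on_undefined)
  et0 <- et0_penman_monteith(weather, sites)
  etc <- etc_penman_monteith(weather, canopy, sites, h_c = h_c)
  out <- inner_join(
    etc %>% select(all_of(c("site_id", "date", "canopy_date")), etc_mm = "et_mm"),
    et0 %>% select(all_of(c("site_id", "date")), et0_mm = "et_mm"),
    by = c("site_id", "date")
  )
  undef <- out$et0_mm < min_et0
  if (any(undef)) {
    if (on_undefined == "error") {
      abort(sprintf(
        "Kc undefined on %d day(s): reference ET below %.2g mm day-1.",
        sum(undef), min_et0
      ))
    }
    warn(sprintf("Dropping %d day(s) with reference ET below the Kc floor.", sum(undef)))
    out <- out[!undef, ]
  }
  out$kc <- out$etc_mm / out$et0_mm
  if ("field_id" %in% names(canopy)) {
    out$field_id <- unique(canopy$field_id)[1]
  }
  out %>%
    select(any_of(c("field_id", "site_id", "date", "kc", "canopy_date",
                    "etc_mm", "et0_mm")))
}

#' Issue crop evapotranspiration forecasts
#'
#' For each forecast issue date `t0` with a matching crop coefficient, the
#' proposed path multiplies the Kc frozen at `t0` by the Hargreaves-Samani
#' reference ET evaluated on (bias-corrected) forecast temperature at each
#' valid day,
#' \deqn{ET_{c\mathrm{-HS}}(t_0 + \Delta t) = K_c(t_0) ET_{0\mathrm{-HS}}(t_0 + \Delta t);}
#' the comparison path re-runs the full one-step Penman-Monteith on the
#' complete set of forecast weather variables with the same held canopy.
#'
#' @param kc Crop-coefficient table from [crop_coefficient()]; `date` is the
#'   issue date.
#' @param forecasts Daily site forecasts (bias-corrected) from
#'   [reduce_daily()] / [apply_bias_correction()] / [sim_forecast_daily()].
#' @param sites Site table.
#' @param canopy Canopy series of the forecast field (for the PM path).
#' @param k_hs Calibrated scaling factor: scalar or tibble `site_id, k_hs`.
#' @param method `"both"` (default), `"hs"` or `"pm"`.
#' @param h_c Crop height for the PM path, m.
#' @return A tibble `field_id?, site_id, issue_date, lead, kc, etc_hs_mm,
#'   etc_pm_mm` (a method not requested is `NA`).
#' @export
forecast_etc <- function(kc, forecasts, sites, canopy = NULL, k_hs = 1,
                         method = c("both", "hs", "pm"), h_c = 0.4) {
  method <- arg_match(method)
  fc <- as_tibble(forecasts) %>%
    mutate(valid_date = .data$issue_date + .data$lead)
  kc_tbl <- kc %>% select(any_of(c("field_id", "site_id", "kc")), issue_date = "date")
  fc <- inner_join(fc, kc_tbl, by = c("site_id", "issue_date"),
                   relationship = "many-to-many")
  if (nrow(fc) == 0) {
    abort("No forecast issue date matches a crop-coefficient date.")
  }
  out <- fc %>%
    select(any_of(c("field_id", "site_id", "issue_date", "lead", "kc", "valid_date")))

  if (method %in% c("both", "hs")) {
    need <- c("t_mean", "t_max", "t_min")
    if (any(!is.finite(as.matrix(fc[need])))) {
      abort("The HS path needs finite forecast t_mean, t_max, t_min.")
    }
    hs_wx <- fc %>%
      select(all_of(c("site_id", "t_max", "t_min", "t_mean")), date = "valid_date")
    et0_hs <- et0_hargreaves(hs_wx, sites, k_hs = k_hs)
    # the joins inside et0_hargreaves preserve the row order of hs_wx
    out$etc_hs_mm <- out$kc * et0_hs$et_mm
  } else {
    out$etc_hs_mm <- NA_real_
  }

  if (method %in% c("both", "pm")) {
    if (is.null(canopy)) abort("The PM path needs the `canopy` series.")
    need <- c("t_mean", "t_max", "t_min", "rh_mean", "ws10", "rs_wm2")
    if (any(!is.finite(as.matrix(fc[need])))) {
      abort("The PM path needs the complete set of forecast weather variables.")
    }
    pm_wx <- fc %>%
      select(all_of(c("site_id", "t_max", "t_min", "t_mean", "rh_mean",
                      "ws10", "rs_wm2")),
             any_of("pressure_kpa"), date = "valid_date")
    # canopy held at the issue date (the state Kc was computed with), not at
    # the valid date: within a 5-day horizon no new image arrives anyway
    held <- hold_canopy(canopy, fc$issue_date)
    etc_pm <- etc_penman_monteith(
      pm_wx, canopy = NULL, sites = sites, h_c = h_c,
      rs_fixed = surface_resistance(held$lai), albedo_fixed = held$albedo
    )
    out$etc_pm_mm <- etc_pm$et_mm
  } else {
    out$etc_pm_mm <- NA_real_
  }

  out %>%
    select(any_of(c("field_id", "site_id", "issue_date", "lead", "kc",
                    "etc_hs_mm", "etc_pm_mm"))) %>%
    arrange(.data$site_id, .data$issue_date, .data$lead)
}

#' Accumulate daily forecasts over irrigation-relevant horizons
#'
#' Partial sums of the per-lead daily values up to each horizon (1, 3 and 5
#' days by default), per issue date -- the quantity a scheduler compares with
#' the planned irrigation volume.
#'
#' @param fc Forecast tibble from [forecast_etc()] (needs every lead
#'   1..max(horizons) per issue date).
#' @param horizons Integer horizons, days.
#' @param cols Value columns to accumulate.
#' @return A long tibble with `horizon` and one `<col>_acc` column per value
#'   column, keyed like `fc` minus `lead`.
#' @export
accumulate_horizons <- function(fc, horizons = c(1, 3, 5),
                                cols = c("etc_hs_mm", "etc_pm_mm")) {
  cols <- intersect(cols, names(fc))
  keys <- intersect(c("field_id", "site_id", "issue_date"), names(fc))
  need <- seq_len(max(horizons))
  check <- fc %>%
    group_by(across(all_of(keys))) %>%
    summarise(ok = all(need %in% .data$lead), .groups = "drop")
  if (!all(check$ok)) {
    abort(sprintf("Missing lead day(s): every lead 1..%d is required per issue date.",
                  max(horizons)))
  }
  purrr::map(horizons, function(h) {
    fc %>%
      filter(.data$lead <= h) %>%
      group_by(across(all_of(keys))) %>%
      summarise(across(all_of(cols), ~ sum(.x), .names = "{.col}_acc"),
                .groups = "drop") %>%
      mutate(horizon = as.integer(h))
  }) %>%
    bind_rows() %>%
    select(all_of(c(keys, "horizon")), everything()) %>%
    arrange(across(all_of(c(keys, "horizon"))))
}
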