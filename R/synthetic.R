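# Synthetic study conditions: 18 Mediterranean stations, a systematic cold
# bias in forecast temperature, lead-growing forecast noise, and a maize
# canopy rising to LAI 5 at flowering with albedo drifting 0.15 -> 0.20.

#' Climatology of the 18 Campania weather stations
#'
#' June-September mean weather observed at 18 automatic weather stations of
#' the Campania region (Southern Italy), spanning coastal plains to Apennine
#' ridges (1-848 m a.s.l.): the site conditions the synthetic weather
#' generator reproduces. Columns beyond the means parameterise the
#' generator's day-to-day structure (seasonal amplitude, AR(1) persistence,
#' noise levels, diurnal temperature range).
#'
#' @return A tibble with one row per station: `site_id, elev_m, lat, lon,
#'   mean_t, mean_ws10, mean_rh, mean_rs_wm2, t_amp, ar1, t_sd, rh_sd,
#'   ws_sd_frac, cloud_sd, drange_mean, drange_sd`.
#' @export
campania_climatology <- function() {
  tibble(
    site_id = sprintf("aws%02d", 1:18),
    elev_m = c(848, 631, 236, 9, 770, 1, 515, 552, 88, 660, 62, 750, 31, 167,
               13, 413, 117, 64),
    lat = c(40.65, 41.20, 41.12, 41.20, 40.86, 40.94, 40.84, 40.26, 40.79,
            40.56, 41.43, 41.42, 41.02, 41.25, 40.64, 40.13, 41.34, 40.61),
    lon = c(14.54, 15.14, 14.83, 13.84, 15.28, 14.02, 15.04, 15.66, 14.16,
            15.24, 13.88, 15.04, 14.34, 14.47, 14.84, 15.46, 14.33, 14.98),
    mean_t = c(20.3, 21.3, 22.8, 23.4, 20.8, 23.7, 20.2, 20.7, 25.7, 21.4,
               23.4, 20.6, 25.8, 23.7, 26.0, 23.2, 22.9, 24.7),
    mean_ws10 = c(2.1, 3.0, 1.9, 1.9, 4.4, 2.5, 1.2, 1.5, 3.2, 4.0, 1.2, 4.2,
                  1.9, 1.9, 2.1, 2.6, 1.1, 1.3),
    mean_rh = c(72.3, 67.6, 68.5, 77.1, 69.5, 76.7, 71.5, 77.0, 74.9, 66.8,
                76.0, 70.3, 67.1, 70.9, 65.5, 71.5, 67.0, 63.3),
    mean_rs_wm2 = c(243.3, 264.1, 262.8, 265.3, 267.9, 268.5, 251.7, 256.9,
                    276.3, 256.4, 240.3, 266.4, 255.9, 260.2, 261.6, 260.8,
                    254.4, 263.7),
    t_amp = 3,
    ar1 = 0.7,
    t_sd = 1.5,
    rh_sd = 8,
    ws_sd_frac = 0.25,
    cloud_sd = 0.12,
    drange_mean = 10,
    drange_sd = 2
  )
}

#' @return Site metadata (`site_id, lat, lon, elev_m`) for the stations of
#'   [campania_climatology()].
#' @rdname campania_climatology
#' @export
campania_sites <- function() {
  campania_climatology() %>% select(all_of(c("site_id", "lat", "lon", "elev_m")))
}

# stationary AR(1) series with marginal standard deviation sd
ar1_series <- function(n, phi, sd) {
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - phi^2)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + rnorm(1, 0, innov_sd)
  x
}

#' Generate daily station weather
#'
#' Simulates daily surface weather per site as a centred seasonal harmonic
#' plus AR(1) anomalies around the site climatology. Temperature extremes are
#' the mean plus/minus half a Gaussian diurnal range; shortwave radiation is
#' a persistent cloudiness fraction times the clear-sky radiation
#' `(0.75 + 2e-5 z) Ra`, so the clear-sky cap holds by construction; relative
#' humidity is clipped to \[20, 98\] %; wind to a 0.2 m s^-1 floor.
#'
#' @param clim Climatology tibble as from [campania_climatology()] (any
#'   subset of rows; missing generator columns fall back to its defaults).
#' @param dates `Date` vector of days to generate (e.g.
#'   [irrigation_season()]).
#' @param seed Integer seed; the whole series is reproducible given it.
#' @return A weather tibble `site_id, date, t_max, t_min, t_mean, rh_mean,
#'   ws10, rs_wm2, pressure_kpa` accepted by every estimator.
#' @export
sim_weather <- function(clim, dates, seed) {
  dates <- as.Date(dates)
  if (length(dates) == 0) abort("`dates` must be non-empty.")
  withr::with_seed(seed, {
    purrr::map(seq_len(nrow(clim)), function(i) {
      s <- clim[i, ]
      get_par <- function(name, default) {
        if (name %in% names(s) && is.finite(s[[name]])) s[[name]] else default
      }
      n <- length(dates)
      doy <- as.integer(strftime(dates, "%j"))
      phi <- get_par("ar1", 0.7)
      seasonal <- get_par("t_amp", 3) * cos(2 * pi * (doy - 213) / 365)
      seasonal <- seasonal - mean(seasonal)
      t_mean <- s$mean_t + seasonal + ar1_series(n, phi, get_par("t_sd", 1.5))
      drange <- pmax(1.5, rnorm(n, get_par("drange_mean", 10), get_par("drange_sd", 2)))
      rh <- pmin(98, pmax(20, s$mean_rh + ar1_series(n, phi, get_par("rh_sd", 8))))
      ws <- pmax(0.2, s$mean_ws10 * (1 + ar1_series(n, phi, get_par("ws_sd_frac", 0.25))))
      ra <- extraterrestrial_radiation(s$lat, doy)
      rso <- (0.75 + 2e-5 * s$elev_m) * ra
      f_base <- min(0.95, max(0.3, wm2_to_mj_day(s$mean_rs_wm2) / mean(rso)))
      f <- pmin(1, pmax(0.2, f_base + ar1_series(n, phi, get_par("cloud_sd", 0.12))))
      tibble(
        site_id = s$site_id,
        date = dates,
        t_max = t_mean + drange / 2,
        t_min = t_mean - drange / 2,
        t_mean = t_mean,
        rh_mean = rh,
        ws10 = ws,
        rs_wm2 = mj_day_to_wm2(f * rso),
        pressure_kpa = NA_real_
      )
    }) %>% bind_rows()
  })
}

#' Forecast error model for the synthetic ensemble
#'
#' Additive error structure of the synthetic numerical-weather-prediction
#' ensemble: a per-variable systematic bias (default: a -0.68 degC cold bias
#' in temperature, none elsewhere), Gaussian noise whose standard deviation
#' grows linearly with lead time, and member-to-member dispersion.
#'
#' @param bias Named numeric, units of each variable (`T` degC, `RH` %,
#'   `WS10` m s^-1, `RS` W m^-2, `P` kPa).
#' @param sd Named numeric, noise sd at lead 1 day.
#' @param lead_growth Fractional sd growth per extra lead day (0.2 = +20 %).
#' @param member_sd Named numeric member dispersion (member-level generator
#'   only); defaults to half of `sd`.
#' @param members Ensemble size (>= 2).
#' @return An object of class `forecast_error_model`.
#' @export
forecast_error_model <- function(bias = c(T = -0.68, RH = 0, WS10 = 0, RS = 0, P = 0),
                                 sd = c(T = 1.0, RH = 7, WS10 = 0.6, RS = 25, P = 0.3),
                                 lead_growth = 0.2,
                                 member_sd = NULL,
                                 members = 16) {
  if (members < 2) abort("`members` must be at least 2.")
  if (any(sd < 0)) abort("Noise standard deviations must be non-negative.")
  if (is.null(member_sd)) member_sd <- sd / 2
  structure(
    list(bias = bias, sd = sd, lead_growth = lead_growth,
         member_sd = member_sd, members = as.integer(members)),
    class = "forecast_error_model"
  )
}

#' @export
print.forecast_error_model <- function(x, ...) {
  cat("<forecast_error_model>", x$members, "members; sd growth",
      sprintf("%+.0f%%/lead day\n", 100 * x$lead_growth))
  print(tibble(variable = names(x$bias), bias = unname(x$bias),
               sd_lead1 = unname(x$sd[names(x$bias)])))
  invisible(x)
}

sd_at_lead <- function(model, variable, lead) {
  model$sd[[variable]] * (1 + model$lead_growth * (lead - 1))
}

#' Generate daily ensemble-reduced forecasts
#'
#' Daily-level synthetic forecasts: for every issue date whose 1..`max(leads)`
#' valid days all lie in the truth series, the forecast equals the truth plus
#' the model bias plus one Gaussian draw at the lead-dependent sd (the
#' ensemble-median equivalent of the member-level generator, applied per
#' day). The temperature draw shifts `t_mean`, `t_max` and `t_min` together.
#' With all sds at zero the forecast is exactly truth + bias.
#'
#' @param truth Observed weather from [sim_weather()] (or measured data).
#' @param model A [forecast_error_model()].
#' @param seed Integer seed.
#' @param leads Integer lead days (default 1:5).
#' @return A tibble shaped like [reduce_daily()] output: `site_id,
#'   issue_date, lead, t_mean, t_max, t_min, rh_mean, ws10, rs_wm2,
#'   pressure_kpa`.
#' @export
sim_forecast_daily <- function(truth, model = forecast_error_model(), seed,
                               leads = 1:5) {
  truth <- as_tibble(truth)
  truth$date <- as.Date(truth$date)
  withr::with_seed(seed, {
    purrr::map(split(truth, truth$site_id), function(tr) {
      tr <- arrange(tr, .data$date)
      issue <- tr$date[vapply(tr$date, function(d) all((d + leads) %in% tr$date), logical(1))]
      if (length(issue) == 0) return(NULL)
      grid <- tidyr::expand_grid(issue_date = issue, lead = as.integer(leads)) %>%
        mutate(valid_date = .data$issue_date + .data$lead) %>%
        inner_join(tr, by = c("valid_date" = "date"))
      ns <- nrow(grid)
      g <- 1 + model$lead_growth * (grid$lead - 1)
      err_t <- model$bias[["T"]] + rnorm(ns, 0, 1) * model$sd[["T"]] * g
      grid %>%
        mutate(
          t_mean = .data$t_mean + err_t,
          t_max = .data$t_max + err_t,
          t_min = .data$t_min + err_t,
          rh_mean = pmin(100, pmax(0, .data$rh_mean + model$bias[["RH"]] +
                                     rnorm(ns, 0, 1) * model$sd[["RH"]] * g)),
          ws10 = pmax(0, .data$ws10 + model$bias[["WS10"]] +
                        rnorm(ns, 0, 1) * model$sd[["WS10"]] * g),
          rs_wm2 = pmax(0, .data$rs_wm2 + model$bias[["RS"]] +
                          rnorm(ns, 0, 1) * model$sd[["RS"]] * g)
        ) %>%
        select(all_of(c("site_id", "issue_date", "lead", "t_mean", "t_max",
                        "t_min", "rh_mean", "ws10", "rs_wm2", "pressure_kpa")))
    }) %>% bind_rows() %>% arrange(.data$site_id, .data$issue_date, .data$lead)
  })
}

#' Generate 3-hourly ensemble member forecasts (long format)
#'
#' Member-level synthetic ensemble output for exercising the full reduction
#' chain: per site, issue date, member, variable and 3-hourly step (hours
#' 0, 3, ..., 21 of each valid day),
#' value = diurnally interpolated truth + bias + lead noise (shared across
#' members) + member noise. Temperature follows a cosine diurnal cycle with
#' the truth's daily range peaking at 15:00; shortwave radiation follows a
#' normalised daylight half-cosine whose mean preserves the daily truth;
#' other variables are flat within the day. Intended for modest problem
#' sizes (the row count is sites x issues x members x variables x leads x 8).
#'
#' @inheritParams sim_forecast_daily
#' @param variables Variables to emit (default all of T, RH, WS10, RS).
#' @return Long tibble `site_id, issue_time, member_id, variable, valid_time,
#'   value` for [reduce_daily()].
#' @export
sim_forecast_members <- function(truth, model = forecast_error_model(), seed,
                                 leads = 1:5,
                                 variables = c("T", "RH", "WS10", "RS")) {
  truth <- as_tibble(truth)
  truth$date <- as.Date(truth$date)
  hours <- seq(0, 21, by = 3)
  rs_w <- pmax(0, cos(2 * pi * (hours - 12) / 24))
  rs_w <- rs_w / mean(rs_w)
  t_w <- cos(2 * pi * (hours - 15) / 24) # zero mean over the 8 steps
  withr::with_seed(seed, {
    purrr::map(split(truth, truth$site_id), function(tr) {
      tr <- arrange(tr, .data$date)
      issue <- tr$date[vapply(tr$date, function(d) all((d + leads) %in% tr$date), logical(1))]
      if (length(issue) == 0) return(NULL)
      purrr::map(as.list(issue), function(t0) {
        purrr::map(as.list(as.integer(leads)), function(lead) {
          day <- tr[tr$date == t0 + lead, ]
          base <- lapply(variables, function(v) {
            daily <- switch(v,
              T = day$t_mean + (day$t_max - day$t_min) / 2 * t_w,
              RH = rep(day$rh_mean, 8),
              WS10 = rep(day$ws10, 8),
              RS = day$rs_wm2 * rs_w,
              P = rep(day$pressure_kpa, 8)
            )
            lead_noise <- rnorm(1, 0, sd_at_lead(model, v, lead))
            vals <- lapply(seq_len(model$members), function(m) {
              daily + model$bias[[v]] + lead_noise +
                rnorm(8, 0, model$member_sd[[v]] * (1 + model$lead_growth * (lead - 1)))
            })
            tibble(
              member_id = rep(seq_len(model$members), each = 8),
              variable = v,
              valid_time = rep(as.POSIXct(t0 + lead, tz = "UTC") + hours * 3600,
                               model$members),
              value = unlist(vals)
            )
          })
          bind_rows(base) %>%
            mutate(site_id = day$site_id, issue_time = as.POSIXct(t0, tz = "UTC"))
        }) %>% bind_rows()
      }) %>% bind_rows()
    }) %>%
      bind_rows() %>%
      select(all_of(c("site_id", "issue_time", "member_id", "variable",
                      "valid_time", "value")))
  })
}

#' Default maize-season sensor
#'
#' A three-band (green/red/NIR) sensor specification with irradiance-style
#' weights (most of the solar irradiance sits in the visible bands) and a
#' soil-line slope of 1.2, matching the forward model used by
#' [sim_canopy()].
#'
#' @return A [sensor_spec()].
#' @export
default_sensor <- function() {
  sensor_spec("synthetic3band", c(green = 0.35, red = 0.45, nir = 0.20),
              soil_line_slope = 1.2)
}

#' Generate a maize canopy season with consistent reflectances
#'
#' A maize LAI season: normalised logistic rise reaching exactly `lai_max`
#' at the flowering day, then a slow exponential decline; albedo linear in
#' LAI between the early-season and full-canopy values. Reflectances are
#' produced by running the CLAIR model forward,
#' `WDVI = WDVI_inf (1 - exp(-alpha* LAI))`, assigning a red reflectance
#' decaying from bare soil with canopy closure and recovering the NIR band
#' from the soil-line identity -- so [retrieve_lai()] on the emitted bands
#' reproduces the emitted LAI exactly.
#'
#' @param year Season year (June 1 - September 30 sampling window).
#' @param field_id Field identifier.
#' @param lai_max Peak leaf area index (default 5, a vigorous maize canopy).
#' @param flowering_doy Day of year of flowering (default 213, Aug 1).
#' @param albedo_range Early-season and full-canopy albedo (default
#'   0.15-0.20).
#' @param clair [clair_params()] of the forward model.
#' @param spec [sensor_spec()] providing the soil-line slope.
#' @param sampling_interval Days between acquisitions (7 for a weekly
#'   revisit, 15 for a fortnightly one).
#' @param growth_scale,growth_offset Logistic steepness (days) and distance
#'   of the inflection before flowering (days).
#' @param decline_rate Post-flowering exponential decline, day^-1.
#' @return A tibble `field_id, date, lai, albedo, rho_red, rho_nir`.
#' @export
sim_canopy <- function(year = 2014, field_id = "field01", lai_max = 5,
                       flowering_doy = 213, albedo_range = c(0.15, 0.20),
                       clair = clair_params(0.35, 0.6),
                       spec = default_sensor(),
                       sampling_interval = 7,
                       growth_scale = 8, growth_offset = 30,
                       decline_rate = 0.01) {
  if (lai_max <= 0) abort("`lai_max` must be positive.")
  if (albedo_range[1] >= albedo_range[2]) {
    abort("`albedo_range` must be increasing (early < full canopy).")
  }
  dates <- seq(as.Date(sprintf("%d-06-01", year)),
               as.Date(sprintf("%d-09-30", year)), by = sampling_interval)
  doy <- as.integer(strftime(dates, "%j"))
  mid <- flowering_doy - growth_offset
  rise <- plogis((doy - mid) / growth_scale) / plogis(growth_offset / growth_scale)
  lai <- if_else(doy <= flowering_doy,
                 lai_max * rise,
                 lai_max * exp(-decline_rate * (doy - flowering_doy)))
  albedo <- albedo_range[1] + diff(albedo_range) * lai / lai_max
  w <- clair$wdvi_inf * (1 - exp(-clair$alpha_star * lai))
  rho_red <- 0.04 + 0.11 * exp(-0.6 * lai)
  rho_nir <- w + spec$soil_line_slope * rho_red
  out <- tibble(
    field_id = field_id, date = dates, lai = lai, albedo = albedo,
    rho_red = rho_red, rho_nir = rho_nir
  )
  # with a green band available, close the albedo identity exactly so that
  # broadband_albedo() on the emitted bands returns the emitted albedo
  wts <- spec$weights
  if ("green" %in% names(wts)) {
    rho_green <- (albedo - wts[["red"]] * rho_red - wts[["nir"]] * rho_nir) /
      wts[["green"]]
    if (any(rho_green < 0 | rho_green > 1)) {
      abort("Green reflectance outside [0, 1]: sensor weights inconsistent with `albedo_range`.")
    }
    out$rho_green <- rho_green
  }
  out
}
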