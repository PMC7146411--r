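# --- input checking shared by the estimators -------------------------------

check_sites <- function(sites) {
  required <- c("site_id", "lat", "lon", "elev_m")
  missing_cols <- setdiff(required, names(sites))
  if (length(missing_cols) > 0) {
    abort(paste0("`sites` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(abs(sites$lat) > 90)) abort("`lat` must lie in [-90, 90].")
  if (any(sites$elev_m <= -430)) abort("`elev_m` must exceed -430 m.")
  sites
}

check_weather <- function(weather) {
  required <- c("site_id", "date", "t_max", "t_min", "rh_mean", "ws10", "rs_wm2")
  missing_cols <- setdiff(required, names(weather))
  if (length(missing_cols) > 0) {
    abort(paste0("`weather` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(weather$t_min > weather$t_max, na.rm = TRUE)) {
    abort("`t_min` must not exceed `t_max`.")
  }
  if (any(weather$rh_mean < 0 | weather$rh_mean > 100, na.rm = TRUE)) {
    abort("`rh_mean` must lie in [0, 100].")
  }
  if (any(weather$ws10 < 0, na.rm = TRUE)) abort("`ws10` must be non-negative.")
  if (any(weather$rs_wm2 < 0, na.rm = TRUE)) abort("`rs_wm2` must be non-negative.")
  weather <- as_tibble(weather)
  # mean temperature defaults to the mid-range of the daily extremes
  if (!"t_mean" %in% names(weather)) weather$t_mean <- NA_real_
  weather$t_mean <- if_else(is.na(weather$t_mean),
                            (weather$t_max + weather$t_min) / 2,
                            weather$t_mean)
  if (!"pressure_kpa" %in% names(weather)) weather$pressure_kpa <- NA_real_
  weather$date <- as.Date(weather$date)
  weather
}

clamp_et <- function(et, method) {
  neg <- sum(et < 0, na.rm = TRUE)
  if (neg > 0) {
    warn(sprintf("%d negative %s value(s) clamped to 0 (longwave-dominated days).",
                 neg, method))
  }
  pmax(et, 0)
}

# full weather + psychrometric frame used by both Penman-Monteith forms
pm_terms <- function(weather, sites, albedo) {
  weather <- check_weather(weather)
  sites <- check_sites(sites)
  wx <- inner_join(weather, sites, by = "site_id")
  if (nrow(wx) < nrow(weather)) {
    abort("Some weather rows have no matching site in `sites`.")
  }
  vp <- vapor_pressures(wx$t_max, wx$t_min, wx$rh_mean)
  ac <- air_constants(wx$elev_m, wx$t_mean, wx$pressure_kpa)
  doy <- as.integer(strftime(wx$date, "%j"))
  wx$ra_mj <- extraterrestrial_radiation(wx$lat, doy)
  wx$rs_mj <- wm2_to_mj_day(wx$rs_wm2)
  wx$ws2 <- wind_2m_from_10m(wx$ws10)
  wx$rn_mj <- net_radiation(wx$rs_mj, albedo, wx$t_max, wx$t_min, vp$e_a,
                            wx$ra_mj, wx$elev_m)
  bind_cols_safe(wx, vp, ac)
}

bind_cols_safe <- function(...) {
  out <- do.call(cbind, lapply(list(...), as.data.frame))
  as_tibble(out)
}

# --- reference evapotranspiration (Penman-Monteith) -------------------------

#' FAO-56 reference evapotranspiration (Penman-Monteith)
#'
#' Daily reference evapotranspiration of the hypothetical grass reference
#' surface (albedo 0.23, height 0.12 m, surface resistance 70 s m^-1), from
#' the standard daily reduced form
#' \deqn{ET_0 = \frac{0.408 \Delta (R_n - G) + \gamma \frac{900}{T+273} u_2 (e_s - e_a)}
#'   {\Delta + \gamma (1 + 0.34 u_2)}}
#' with soil heat flux G = 0 at the daily scale and wind converted from 10 m
#' to 2 m. 0.408 is 1/lambda with lambda = 2.45 MJ kg^-1. The same calm-wind
#' floor used in the resistance-based crop form (`ws2 >= 0.1` m s^-1) is
#' applied here, so the two formulations remain consistent as the wind dies.
#'
#' @param weather Daily weather tibble: `site_id, date, t_max, t_min,
#'   rh_mean, ws10, rs_wm2` and optionally `t_mean`, `pressure_kpa`
#'   (shortwave radiation in W m^-2 as stations report it).
#' @param sites Site table: `site_id, lat, lon, elev_m`.
#' @param ws2_floor Calm-wind floor on the 2 m wind speed, m s^-1.
#' @return A tibble `site_id, date, method, et_mm` with `method = "et0_pm"`;
#'   rare negative values are clamped to 0 with a warning.
#' @export
et0_penman_monteith <- function(weather, sites, ws2_floor = 0.1) {
  wx <- pm_terms(weather, sites, albedo = 0.23)
  ws2 <- pmax(wx$ws2, ws2_floor)
  num <- 0.408 * wx$delta * wx$rn_mj +
    wx$gamma * 900 / (wx$t_mean + 273) * ws2 * (wx$e_s - wx$e_a)
  den <- wx$delta + wx$gamma * (1 + 0.34 * ws2)
  tibble(
    site_id = wx$site_id,
    date = wx$date,
    method = "et0_pm",
    et_mm = clamp_et(num / den, "ET0-PM")
  )
}

# --- canopy resistances -----------------------------------------------------

#' Aerodynamic resistance of a uniform crop
#'
#' Log-profile aerodynamic resistance between the canopy and the 2 m
#' measurement height, with roughness lengths 0.123 h and 0.0123 h and a
#' displacement height of two thirds of the crop height h:
#' \deqn{r_a = \ln\frac{2 - \frac{2}{3}h}{0.123 h} \cdot
#'   \ln\frac{2 - \frac{2}{3}h}{0.0123 h} / (0.41^2 u_2)}
#'
#' @param h_c Crop height, m; must satisfy `2 - (2/3) h_c > 0`.
#' @param ws2 Wind speed at 2 m, m s^-1, strictly positive (callers apply a
#'   calm-wind floor before this point).
#' @return Aerodynamic resistance, s m^-1.
#' @examples
#' aerodynamic_resistance(0.12, 1) # ~ 208, the reference-crop value
#' @export
aerodynamic_resistance <- function(h_c, ws2) {
  if (any(h_c <= 0 | 2 - 2 / 3 * h_c <= 0)) {
    abort("`h_c` must lie in (0, 3) m so the 2 m level is above the canopy.")
  }
  if (any(ws2 <= 0)) {
    abort("Calm wind: `ws2` must be strictly positive (apply a floor upstream).")
  }
  z <- 2 - 2 / 3 * h_c
  log(z / (0.123 * h_c)) * log(z / (0.0123 * h_c)) / (0.41^2 * ws2)
}

#' Surface resistance from leaf area index
#'
#' Piecewise bulk surface resistance of a transpiring canopy: `200 / LAI` up
#' to LAI = 4, then a 50 s m^-1 plateau (continuous at LAI = 4).
#'
#' @param lai Leaf area index, m^2 m^-2, strictly positive.
#' @return Surface resistance, s m^-1.
#' @examples
#' surface_resistance(1) # 200
#' surface_resistance(4) # 50
#' @export
surface_resistance <- function(lai) {
  if (any(lai <= 0)) {
    abort("`lai` must be strictly positive (no-transpiration degenerate case).")
  }
  if_else(lai <= 4, 200 / lai, 50)
}

# --- one-step crop evapotranspiration ---------------------------------------

#' One-step crop evapotranspiration (Penman-Monteith with remote canopy)
#'
#' Crop potential evapotranspiration under standard conditions by inserting
#' the remotely sensed canopy parameters directly into the full
#' Penman-Monteith equation (the "one-step" approach):
#' \deqn{ET_c = \frac{86400}{\lambda}
#'   \frac{\Delta (R_n - G) + \rho c_p (e_s - e_a)/r_a}
#'        {\Delta + \gamma (1 + r_s/r_a)}}
#' with the canopy albedo in the net radiation, `r_s` from LAI via
#' [surface_resistance()] and `r_a` from the crop height via
#' [aerodynamic_resistance()]. Flux terms are harmonised to W m^-2 before the
#' `86400 / lambda` conversion to water depth. Canopy parameters are held
#' constant between acquisitions ([hold_canopy()]).
#'
#' @inheritParams et0_penman_monteith
#' @param canopy Canopy series for one field: `date, lai, albedo` (strictly
#'   increasing dates). Must start on or before the first weather date. May
#'   be `NULL` when both `rs_fixed` and `albedo_fixed` are given.
#' @param h_c Crop height, m (default 0.4; ET is insensitive in 0.1-0.6 m).
#' @param rs_fixed Optional surface resistance vector, s m^-1, overriding the
#'   LAI rule (used e.g. to reproduce the grass reference configuration, or
#'   to freeze the canopy at a forecast issue date).
#' @param albedo_fixed Optional albedo vector overriding the canopy series.
#' @param ws2_floor Calm-wind floor applied to the 2 m wind speed, m s^-1.
#' @return A tibble `site_id, date, method, et_mm, lai, albedo, canopy_date`
#'   with `method = "etc_pm"`.
#' @export
etc_penman_monteith <- function(weather, canopy, sites, h_c = 0.4,
                                rs_fixed = NULL, albedo_fixed = NULL,
                                ws2_floor = 0.1) {
  weather <- check_weather(weather)
  if (is.null(canopy)) {
    if (is.null(rs_fixed) || is.null(albedo_fixed)) {
      abort("Without a `canopy` series both `rs_fixed` and `albedo_fixed` are required.")
    }
    held <- tibble(date = weather$date, canopy_date = as.Date(NA),
                   lai = NA_real_, albedo = NA_real_)
  } else {
    held <- hold_canopy(canopy, weather$date)
  }
  albedo <- if (is.null(albedo_fixed)) held$albedo else albedo_fixed
  wx <- pm_terms(weather, sites, albedo = albedo)
  r_s <- if (is.null(rs_fixed)) surface_resistance(held$lai) else rs_fixed
  ws2 <- pmax(wx$ws2, ws2_floor)
  r_a <- aerodynamic_resistance(h_c, ws2)
  rn_w <- mj_day_to_wm2(wx$rn_mj)                  # W m-2
  cp_j <- wx$c_p * 1e6                             # J kg-1 K-1
  flux <- (wx$delta * rn_w + wx$rho_air * cp_j * (wx$e_s - wx$e_a) / r_a) /
    (wx$delta + wx$gamma * (1 + r_s / r_a))        # W m-2
  et <- flux * 86400 / (wx$lam * 1e6)              # mm day-1
  tibble(
    site_id = wx$site_id,
    date = wx$date,
    method = "etc_pm",
    et_mm = clamp_et(et, "ETc-PM"),
    lai = held$lai,
    albedo = albedo,
    canopy_date = held$canopy_date
  )
}

# --- Hargreaves-Samani ------------------------------------------------------

#' Hargreaves-Samani reference evapotranspiration
#'
#' Temperature-only reference evapotranspiration,
#' \deqn{ET_{0\mathrm{-HS}} = k_{HS} \cdot 0.0023 (T + 17.8)
#'   \sqrt{T_{max} - T_{min}} \cdot 0.408 R_a}
#' with the extraterrestrial radiation from site latitude and date. The
#' scaling factor `k_hs` (1 in the original formulation) should be locally
#' calibrated against Penman-Monteith reference ET ([calibrate_khs()]).
#'
#' @param weather Tibble with `site_id, date, t_max, t_min` and optionally
#'   `t_mean` (filled as the mid-range if absent).
#' @param sites Site table: `site_id, lat, lon, elev_m`.
#' @param k_hs Either a single scaling factor or a tibble `site_id, k_hs`.
#' @return A tibble `site_id, date, method, et_mm` with `method = "et0_hs"`
#'   (0 when the mean temperature falls below -17.8 degC).
#' @export
et0_hargreaves <- function(weather, sites, k_hs = 1) {
  required <- c("site_id", "date", "t_max", "t_min")
  missing_cols <- setdiff(required, names(weather))
  if (length(missing_cols) > 0) {
    abort(paste0("`weather` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(weather$t_min > weather$t_max, na.rm = TRUE)) {
    abort("`t_min` must not exceed `t_max`.")
  }
  sites <- check_sites(sites)
  wx <- as_tibble(weather)
  wx$date <- as.Date(wx$date)
  if (!"t_mean" %in% names(wx)) wx$t_mean <- NA_real_
  wx$t_mean <- if_else(is.na(wx$t_mean), (wx$t_max + wx$t_min) / 2, wx$t_mean)
  if (is.data.frame(k_hs)) {
    wx <- inner_join(wx, select(k_hs, all_of(c("site_id", "k_hs"))), by = "site_id")
  } else {
    if (any(k_hs <= 0)) abort("`k_hs` must be positive.")
    wx$k_hs <- k_hs
  }
  wx <- inner_join(wx, sites, by = "site_id")
  ra <- extraterrestrial_radiation(wx$lat, as.integer(strftime(wx$date, "%j")))
  et <- wx$k_hs * 0.0023 * pmax(wx$t_mean + 17.8, 0) *
    sqrt(wx$t_max - wx$t_min) * 0.408 * ra
  tibble(site_id = wx$site_id, date = wx$date, method = "et0_hs", et_mm = et)
}
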