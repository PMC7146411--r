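#' Saturation vapour pressure at a given air temperature
#'
#' Tetens-type exponential used throughout the FAO-56 procedure:
#' \eqn{e^o(T) = 0.6108 \exp(17.27 T / (T + 237.3))}.
#'
#' @param t Air temperature, degC.
#' @return Saturation vapour pressure, kPa.
#' @export
saturation_vp <- function(t) {
  0.6108 * exp(17.27 * t / (t + 237.3))
}

#' Daily vapour pressures and vapour-pressure-curve slope
#'
#' Computes the FAO-56 daily saturation vapour pressure (mean of the values at
#' the daily temperature extremes), the actual vapour pressure from mean
#' relative humidity, and the slope of the saturation curve evaluated at the
#' daily mean temperature.
#'
#' @param t_max,t_min Daily maximum and minimum air temperature, degC.
#' @param rh_mean Daily mean relative humidity, percent in \[0, 100\].
#' @return A tibble with columns `e_s`, `e_a` (kPa) and `delta` (kPa degC^-1),
#'   one row per input element.
#' @examples
#' vapor_pressures(20, 20, 100) # e_s = e_a ~ 2.338 kPa
#' @export
vapor_pressures <- function(t_max, t_min, rh_mean) {
  if (any(!is.finite(t_max)) || any(!is.finite(t_min)) || any(!is.finite(rh_mean))) {
    abort("`t_max`, `t_min` and `rh_mean` must be finite.")
  }
  if (any(t_min > t_max)) {
    abort("`t_min` must not exceed `t_max`.")
  }
  if (any(rh_mean < 0 | rh_mean > 100)) {
    abort("`rh_mean` must lie in [0, 100] percent.")
  }
  t_mean <- (t_max + t_min) / 2
  e_s <- (saturation_vp(t_max) + saturation_vp(t_min)) / 2
  tibble(
    e_s = e_s,
    e_a = rh_mean / 100 * e_s,
    delta = 4098 * saturation_vp(t_mean) / (t_mean + 237.3)^2
  )
}

#' Barometric pressure, psychrometric constant and air density
#'
#' FAO-56 closure constants for the Penman-Monteith equation. Pressure, when
#' not measured, follows the barometric formula
#' \eqn{P = 101.3 ((293 - 0.0065 z)/293)^{5.26}}; the psychrometric constant
#' is \eqn{\gamma = 0.000665 P}; air density comes from the ideal-gas law at
#' the virtual temperature; the latent heat of vaporisation is held at
#' 2.45 MJ kg^-1 and specific heat at 1.013e-3 MJ kg^-1 degC^-1.
#'
#' @param elevation Site elevation, m above sea level.
#' @param t_mean Daily mean air temperature, degC.
#' @param pressure Optional measured barometric pressure, kPa; overrides the
#'   elevation-based estimate where non-`NA`.
#' @return A tibble with columns `pressure` (kPa), `gamma` (kPa degC^-1),
#'   `lam` (MJ kg^-1), `rho_air` (kg m^-3), `c_p` (MJ kg^-1 degC^-1).
#' @examples
#' air_constants(0, 20) # pressure ~ 101.3 kPa, gamma ~ 0.0674
#' @export
air_constants <- function(elevation, t_mean, pressure = NULL) {
  if (any(!is.finite(elevation)) || any(!is.finite(t_mean))) {
    abort("`elevation` and `t_mean` must be finite.")
  }
  p_est <- 101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
  if (!is.null(pressure)) {
    p_est <- if_else(is.finite(pressure), as.numeric(pressure), p_est)
  }
  tibble(
    pressure = p_est,
    gamma = 0.000665 * p_est,
    lam = 2.45,
    # 3.486 = 1/(0.287 kJ kg-1 K-1); virtual temperature 1.01 (T + 273)
    rho_air = 3.486 * p_est / (1.01 * (t_mean + 273)),
    c_p = 1.013e-3
  )
}

#' Convert 10 m wind speed to the 2 m reference height
#'
#' Logarithmic wind profile over short grass,
#' \eqn{u_2 = u_{10} \cdot 4.87 / \ln(67.8 \cdot 10 - 5.42)}, a constant
#' factor of about 0.75.
#'
#' @param ws10 Wind speed measured at 10 m, m s^-1.
#' @return Wind speed at 2 m, m s^-1.
#' @export
wind_2m_from_10m <- function(ws10) {
  if (any(ws10 < 0, na.rm = TRUE)) {
    abort("Wind speed must be non-negative.")
  }
  ws10 * 4.87 / log(67.8 * 10 - 5.42)
}

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation on a horizontal plane from FAO-56 solar
#' geometry: inverse relative Earth-Sun distance, solar declination and sunset
#' hour angle. The sunset-angle argument is clamped to \[-1, 1\] so polar
#' night returns exactly zero.
#'
#' @param latitude Degrees north, in \[-90, 90\].
#' @param day_of_year Integer day of year, 1..366. Recycled against
#'   `latitude`.
#' @return Extraterrestrial radiation, MJ m^-2 day^-1 (non-negative).
#' @examples
#' extraterrestrial_radiation(40, 196) # ~ 40.8 mid-July at 40 N
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    abort("`latitude` must lie in [-90, 90] degrees.")
  }
  if (any(day_of_year < 1 | day_of_year > 366, na.rm = TRUE)) {
    abort("`day_of_year` must lie in 1..366.")
  }
  phi <- latitude * pi / 180
  j <- day_of_year
  dr <- 1 + 0.033 * cos(2 * pi / 365 * j)
  dec <- 0.409 * sin(2 * pi / 365 * j - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  pmax(ra, 0)
}

#' Daily net radiation at the crop surface
#'
#' Net shortwave minus net longwave radiation. The shortwave term is
#' \eqn{(1 - \alpha) R_s} with the surface albedo either the grass reference
#' value 0.23 or a remotely sensed crop albedo. The longwave term follows the
#' FAO-56 formulation from the temperature extremes, actual vapour pressure
#' and relative shortwave ratio `rs / rso`, with the clear-sky radiation
#' `rso = (0.75 + 2e-5 z) Ra`. The ratio is clamped to \[0.3, 1\] (and treated
#' as 1 when `ra` is zero) to keep the longwave loss physical on overcast or
#' polar-night days.
#'
#' @param rs Incoming shortwave radiation, MJ m^-2 day^-1.
#' @param albedo Broadband surface albedo in \[0, 1).
#' @param t_max,t_min Daily temperature extremes, degC.
#' @param e_a Actual vapour pressure, kPa.
#' @param ra Extraterrestrial radiation, MJ m^-2 day^-1.
#' @param elevation Site elevation, m.
#' @return Net radiation, MJ m^-2 day^-1.
#' @export
net_radiation <- function(rs, albedo, t_max, t_min, e_a, ra, elevation) {
  if (any(albedo < 0 | albedo >= 1, na.rm = TRUE)) {
    abort("`albedo` must lie in [0, 1).")
  }
  if (any(rs < 0, na.rm = TRUE)) {
    abort("`rs` must be non-negative.")
  }
  rso <- (0.75 + 2e-5 * elevation) * ra
  ratio <- if_else(rso > 0, pmin(1, pmax(0.3, rs / rso)), 1)
  sigma <- 4.903e-9 # MJ K-4 m-2 day-1
  rnl <- sigma * ((t_max + 273.16)^4 + (t_min + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(e_a)) * (1.35 * ratio - 0.35)
  (1 - albedo) * rs - rnl
}
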