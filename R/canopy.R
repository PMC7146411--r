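#' Describe a multispectral sensor
#'
#' Holds the band weights used for broadband albedo and the soil-line slope
#' used by the weighted difference vegetation index (WDVI). Weights are the
#' fractions of solar irradiance falling in each band and are normalised to
#' sum to one.
#'
#' @param sensor_id Character name, e.g. `"deimos1"`.
#' @param weights Named numeric vector of non-negative band weights; names are
#'   band ids (`"red"`, `"nir"`, ...). Normalised internally.
#' @param soil_line_slope Ratio of NIR to red reflectance of bare soil
#'   (the soil-line slope `C` in WDVI = rho_nir - C * rho_red); must be > 0.
#' @return An object of class `sensor_spec`.
#' @examples
#' sensor_spec("deimos1", c(green = 0.28, red = 0.33, nir = 0.39))
#' @export
sensor_spec <- function(sensor_id, weights, soil_line_slope = 1.2) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort("`weights` must be a fully named numeric vector.")
  }
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("Band weights must be non-negative with a positive sum.")
  }
  if (soil_line_slope <= 0) {
    abort("`soil_line_slope` must be positive.")
  }
  structure(
    list(
      sensor_id = sensor_id,
      weights = weights / sum(weights),
      soil_line_slope = soil_line_slope
    ),
    class = "sensor_spec"
  )
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat("<sensor_spec> ", x$sensor_id, "\n", sep = "")
  cat("  bands:", paste(sprintf("%s=%.3f", names(x$weights), x$weights), collapse = ", "), "\n")
  cat("  soil-line slope C =", x$soil_line_slope, "\n")
  invisible(x)
}

#' CLAIR model parameters
#'
#' The CLAIR model maps the weighted difference vegetation index to leaf area
#' index through a saturating exponential,
#' \eqn{LAI = -(1/\alpha^*) \ln(1 - WDVI / WDVI_\infty)}.
#'
#' @param alpha_star Extinction/scattering coefficient (> 0); 0.35 is the
#'   value validated for maize in Southern Italy.
#' @param wdvi_inf Asymptotic WDVI of a closed canopy, in (0, 1\]. Site/sensor
#'   specific; no universal default exists, so it must be supplied.
#' @return An object of class `clair_params`.
#' @export
clair_params <- function(alpha_star = 0.35, wdvi_inf) {
  if (missing(wdvi_inf)) {
    abort("`wdvi_inf` has no default: supply the calibrated asymptotic WDVI.")
  }
  if (alpha_star <= 0) abort("`alpha_star` must be positive.")
  if (wdvi_inf <= 0 || wdvi_inf > 1) abort("`wdvi_inf` must lie in (0, 1].")
  structure(list(alpha_star = alpha_star, wdvi_inf = wdvi_inf),
            class = "clair_params")
}

#' @export
print.clair_params <- function(x, ...) {
  cat(sprintf("<clair_params> alpha* = %g, WDVI_inf = %g\n", x$alpha_star, x$wdvi_inf))
  invisible(x)
}

#' Weighted difference vegetation index
#'
#' Soil-line-corrected difference of near-infrared and red reflectance,
#' `WDVI = rho_nir - C * rho_red`.
#'
#' @param rho_red,rho_nir Surface reflectances in \[0, 1\].
#' @param soil_line_slope Soil-line slope C (> 0).
#' @return WDVI (dimensionless).
#' @export
wdvi <- function(rho_red, rho_nir, soil_line_slope = 1.2) {
  if (any(rho_red < 0 | rho_red > 1 | rho_nir < 0 | rho_nir > 1, na.rm = TRUE)) {
    abort("Reflectances must lie in [0, 1].")
  }
  rho_nir - soil_line_slope * rho_red
}

#' Broadband albedo from band reflectances
#'
#' Irradiance-weighted total of the spectral surface reflectances,
#' \eqn{\alpha = \sum_b \rho_b \omega_b}, with the sensor's normalised band
#' weights. Accepts either a data frame carrying one `rho_<band>` column per
#' sensor band (a column `albedo` is appended) or a named numeric vector of
#' reflectances (a scalar is returned).
#'
#' @param x A data frame with `rho_<band>` columns, or a named numeric vector
#'   keyed by band id.
#' @param spec A [sensor_spec()].
#' @return `x` with an `albedo` column, or a numeric scalar.
#' @examples
#' s <- sensor_spec("toy", c(red = 1))
#' broadband_albedo(c(red = 0.2), s) # 0.2
#' @export
broadband_albedo <- function(x, spec) {
  stopifnot(inherits(spec, "sensor_spec"))
  bands <- names(spec$weights)
  if (is.data.frame(x)) {
    cols <- paste0("rho_", bands)
    missing_cols <- setdiff(cols, names(x))
    if (length(missing_cols) > 0) {
      abort(paste0("Missing reflectance column(s): ", paste(missing_cols, collapse = ", ")))
    }
    m <- as.matrix(x[cols])
    if (any(m < 0 | m > 1, na.rm = TRUE)) abort("Reflectances must lie in [0, 1].")
    x$albedo <- as.numeric(m %*% spec$weights)
    as_tibble(x)
  } else {
    missing_bands <- setdiff(bands, names(x))
    if (length(missing_bands) > 0) {
      abort(paste0("Missing band(s): ", paste(missing_bands, collapse = ", ")))
    }
    if (any(x < 0 | x > 1)) abort("Reflectances must lie in [0, 1].")
    sum(x[bands] * spec$weights)
  }
}

#' Retrieve leaf area index from red/NIR reflectance (CLAIR)
#'
#' Inverts the CLAIR exponential,
#' \eqn{LAI = -(1/\alpha^*)\ln(1 - WDVI/WDVI_\infty)}. Negative WDVI (bare or
#' wet soil darker than the soil line) clamps to LAI = 0; WDVI at or beyond
#' the asymptote signals reflectance inconsistent with the model and errors.
#'
#' @param rho_red,rho_nir Surface reflectances in \[0, 1\].
#' @param spec A [sensor_spec()] (supplies the soil-line slope).
#' @param params A [clair_params()].
#' @return Leaf area index, m^2 m^-2 (>= 0).
#' @export
retrieve_lai <- function(rho_red, rho_nir, spec, params) {
  stopifnot(inherits(spec, "sensor_spec"), inherits(params, "clair_params"))
  w <- wdvi(rho_red, rho_nir, spec$soil_line_slope)
  if (any(w >= params$wdvi_inf, na.rm = TRUE)) {
    abort(paste0(
      "WDVI at or above the asymptote WDVI_inf = ", params$wdvi_inf,
      ": reflectance inconsistent with the CLAIR model (saturation)."
    ))
  }
  if_else(w <= 0, 0, -(1 / params$alpha_star) * log(1 - w / params$wdvi_inf))
}

#' Turn a reflectance table into a canopy state table
#'
#' Applies [retrieve_lai()] and [broadband_albedo()] row-wise to a
#' reflectance table (columns `field_id`, `date`, `rho_red`, `rho_nir`, plus
#' any extra `rho_<band>` columns the sensor defines).
#'
#' @param reflectance A data frame of per-field, per-date mean surface
#'   reflectances.
#' @param spec A [sensor_spec()].
#' @param params A [clair_params()].
#' @return A tibble `field_id, date, lai, albedo` ordered by field and date.
#' @export
retrieve_canopy <- function(reflectance, spec, params) {
  required <- c("field_id", "date", "rho_red", "rho_nir")
  missing_cols <- setdiff(required, names(reflectance))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  reflectance %>%
    broadband_albedo(spec) %>%
    mutate(lai = retrieve_lai(.data$rho_red, .data$rho_nir, spec, params)) %>%
    select(all_of(c("field_id", "date", "lai", "albedo"))) %>%
    arrange(.data$field_id, .data$date)
}

#' Hold canopy parameters constant between satellite passes
#'
#' Canopy parameters are updated when a new multispectral image is processed
#' and kept constant until the next acquisition: a step function
#' (forward fill). For each query date the most recent state with
#' `date <= query_date` is returned.
#'
#' @param series A data frame with columns `date`, `lai`, `albedo` (one
#'   field), strictly increasing dates.
#' @param query_date Date vector, each on or after the first observation.
#' @return A tibble with one row per query date: `date` (the query),
#'   `canopy_date` (the acquisition used), `lai`, `albedo`.
#' @export
hold_canopy <- function(series, query_date) {
  if (nrow(series) == 0) abort("`series` must be non-empty.")
  series <- arrange(series, .data$date)
  if (any(duplicated(series$date))) {
    abort("`series` dates must be strictly increasing.")
  }
  query_date <- as.Date(query_date)
  if (any(query_date < min(series$date))) {
    abort("Query date precedes the first canopy observation.")
  }
  idx <- findInterval(as.numeric(query_date), as.numeric(series$date))
  tibble(
    date = query_date,
    canopy_date = series$date[idx],
    lai = series$lai[idx],
    albedo = series$albedo[idx]
  )
}
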