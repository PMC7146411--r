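# Orchestration: the synthetic end-to-end experiment, a YAML-configured
# command runner, and schema-checked CSV I/O.

#' Run the full synthetic forecasting experiment
#'
#' The desk-scale replica of the complete methodology: synthetic weather at
#' up to 18 Mediterranean stations, local Hargreaves-Samani calibration on
#' four past irrigation seasons, synthetic ensemble forecasts with a cold
#' temperature bias fitted and removed on those seasons, canopy seasons for
#' two maize fields (weekly and fortnightly revisit), daily crop-coefficient
#' update, 1-5 day ETc forecasts by both the temperature-only (HS) and the
#' full-variable (PM) path, and BIAS/RMSE verification per lead and per
#' 1/3/5-day accumulation horizon against the one-step best estimate.
#'
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param n_sites Number of stations (rows of [campania_climatology()]).
#' @param year Evaluation season year; calibration uses the four preceding
#'   years.
#' @param error_model A [forecast_error_model()].
#' @param leads Integer lead days.
#' @param horizons Accumulation horizons, days.
#' @param fields Canopy field descriptions: a tibble with columns
#'   `field_id, lai_max, sampling_interval`.
#' @return A list: `skill_daily` (per site/field/method/lead), `skill_acc`
#'   (per site/field/method/horizon), `khs` (`khs_fit`), `bias_table`,
#'   `forecasts`, `best_estimate`, `kc`.
#' @export
run_synthetic_experiment <- function(seed, n_sites = 18, year = 2014,
                                     error_model = forecast_error_model(),
                                     leads = 1:5, horizons = c(1, 3, 5),
                                     fields = tibble(
                                       field_id = c("field01", "field02"),
                                       lai_max = c(5, 3.5),
                                       sampling_interval = c(7, 15)
                                     )) {
  clim <- head(campania_climatology(), n_sites)
  sites <- clim %>% select(all_of(c("site_id", "lat", "lon", "elev_m")))

  # --- local calibration on the four preceding irrigation seasons ----------
  calib_dates <- irrigation_season((year - 4):(year - 1))
  wx_cal <- sim_weather(clim, calib_dates, seed = seed + 1L)
  calib_pairs <- inner_join(
    et0_hargreaves(wx_cal, sites, k_hs = 1) %>%
      select(all_of(c("site_id", "date")), et0_hs_unit = "et_mm"),
    et0_penman_monteith(wx_cal, sites) %>%
      select(all_of(c("site_id", "date")), et0_pm = "et_mm"),
    by = c("site_id", "date")
  )
  khs <- calibrate_khs(calib_pairs)

  # --- temperature bias fitted on the same reference seasons ---------------
  fc_cal <- sim_forecast_daily(wx_cal, error_model, seed = seed + 2L, leads = leads)
  bias_table <- fit_mean_bias(fc_cal, wx_cal, variable = "T")

  # --- evaluation season ---------------------------------------------------
  wx_eval <- sim_weather(clim, irrigation_season(year), seed = seed + 3L)
  fc_eval <- sim_forecast_daily(wx_eval, error_model, seed = seed + 4L, leads = leads) %>%
    apply_bias_correction(bias_table)

  canopies <- purrr::pmap(fields, function(field_id, lai_max, sampling_interval) {
    sim_canopy(year = year, field_id = field_id, lai_max = lai_max,
               sampling_interval = sampling_interval)
  })

  per_field <- purrr::map(canopies, function(cn) {
    kc <- crop_coefficient(wx_eval, cn, sites, on_undefined = "drop")
    fc <- forecast_etc(kc, fc_eval, sites, canopy = cn,
                       k_hs = tidy(khs), method = "both")
    best <- etc_penman_monteith(wx_eval, cn, sites) %>%
      select(all_of(c("site_id", "date")), etc_obs_mm = "et_mm") %>%
      mutate(field_id = cn$field_id[1])
    list(kc = kc, fc = fc, best = best)
  })
  kc_all <- bind_rows(purrr::map(per_field, "kc"))
  fc_all <- bind_rows(purrr::map(per_field, "fc"))
  best_all <- bind_rows(purrr::map(per_field, "best"))

  # daily skill per lead: forecast valid day vs best estimate of that day
  daily_pairs <- fc_all %>%
    mutate(valid_date = .data$issue_date + .data$lead) %>%
    inner_join(best_all, by = c("field_id", "site_id", "valid_date" = "date"))
  skill_daily <- bind_rows(
    skill_scores(daily_pairs, "etc_hs_mm", "etc_obs_mm",
                 by = c("field_id", "site_id", "lead")) %>%
      mutate(method = "etc_hs"),
    skill_scores(daily_pairs, "etc_pm_mm", "etc_obs_mm",
                 by = c("field_id", "site_id", "lead")) %>%
      mutate(method = "etc_pm")
  )

  # accumulated skill: the best estimate accumulated over the same windows
  fc_acc <- accumulate_horizons(fc_all, horizons = horizons)
  best_per_lead <- fc_all %>%
    select(all_of(c("field_id", "site_id", "issue_date", "lead"))) %>%
    mutate(valid_date = .data$issue_date + .data$lead) %>%
    inner_join(best_all, by = c("field_id", "site_id", "valid_date" = "date"))
  best_acc <- accumulate_horizons(best_per_lead, horizons = horizons,
                                  cols = "etc_obs_mm")
  acc_pairs <- inner_join(
    fc_acc, best_acc,
    by = c("field_id", "site_id", "issue_date", "horizon")
  )
  skill_acc <- bind_rows(
    skill_scores(acc_pairs, "etc_hs_mm_acc", "etc_obs_mm_acc",
                 by = c("field_id", "site_id", "horizon")) %>%
      mutate(method = "etc_hs"),
    skill_scores(acc_pairs, "etc_pm_mm_acc", "etc_obs_mm_acc",
                 by = c("field_id", "site_id", "horizon")) %>%
      mutate(method = "etc_pm")
  )

  list(
    skill_daily = skill_daily, skill_acc = skill_acc, khs = khs,
    bias_table = bias_table, forecasts = fc_all, best_estimate = best_all,
    kc = kc_all, weather = wx_eval, forecast_daily = fc_eval
  )
}

# --- configuration ----------------------------------------------------------

#' Default pipeline configuration
#'
#' Nested key/value defaults for [run_pipeline()]: file names inside the run
#' directory, CLAIR and sensor parameters, calibration floor, forecast
#' settings and the synthetic-experiment block. Any subset can be overridden
#' by a YAML file via [load_config()].
#'
#' @return A named list.
#' @export
default_config <- function() {
  list(
    paths = list(
      sites = "sites.csv", weather = "weather.csv",
      forecasts = "forecasts.csv", reflectance = "reflectance.csv",
      canopy = "canopy.csv", khs = "khs.json", bias = "bias.json",
      forecast_out = "etc_forecast.csv", skill = "skill.csv",
      summary = "skill_summary.json"
    ),
    sensor = list(sensor_id = "synthetic3band",
                  weights = list(green = 0.35, red = 0.45, nir = 0.20),
                  soil_line_slope = 1.2),
    clair = list(alpha_star = 0.35, wdvi_inf = 0.6),
    calibration = list(min_days = 30),
    forecast = list(h_c = 0.4, method = "both", horizons = c(1, 3, 5)),
    simulate = list(seed = 1, n_sites = 18, year = 2014, leads = 1:5)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a YAML configuration over the defaults
#'
#' @param path YAML file; keys mirror [default_config()].
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  merge_config(default_config(), yaml::read_yaml(path))
}

config_sensor <- function(config) {
  sensor_spec(config$sensor$sensor_id, unlist(config$sensor$weights),
              config$sensor$soil_line_slope)
}

config_clair <- function(config) {
  clair_params(config$clair$alpha_star, config$clair$wdvi_inf)
}

# --- schema-checked CSV readers --------------------------------------------

csv_schemas <- list(
  sites = c("site_id", "lat", "lon", "elev_m"),
  weather = c("site_id", "date", "t_max", "t_min", "t_mean", "rh_mean",
              "ws10", "rs_wm2", "pressure_kpa"),
  forecasts = c("site_id", "issue_date", "lead", "t_mean", "t_max", "t_min",
                "rh_mean", "ws10", "rs_wm2", "pressure_kpa"),
  reflectance = c("field_id", "date", "sensor_id", "rho_red", "rho_nir"),
  canopy = c("field_id", "date", "lai", "albedo")
)

read_pipeline_csv <- function(path, schema) {
  expected <- csv_schemas[[schema]]
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  extra <- setdiff(names(d), c(expected, paste0("rho_", c("green", "blue", "swir"))))
  missing_cols <- setdiff(expected, names(d))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s: missing column(s) %s.", basename(path),
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(extra) > 0) {
    abort(sprintf("%s: unknown column(s) %s.", basename(path),
                  paste(extra, collapse = ", ")))
  }
  d
}

# --- command runner ---------------------------------------------------------

#' Run one pipeline command against a run directory
#'
#' Reproducible command surface over the package functions. All inputs and
#' outputs live under `dir` with the file names of the configuration:
#'
#' * `simulate` -- write synthetic sites, weather (calibration + evaluation
#'   seasons), daily forecasts and reflectance acquisitions.
#' * `retrieve-canopy` -- invert reflectances to a LAI/albedo canopy table.
#' * `calibrate` -- fit the Hargreaves-Samani scaling factor per site and the
#'   temperature bias table from weather and forecasts of the reference
#'   seasons (valid dates before the evaluation year).
#' * `forecast` -- issue bias-corrected 1-5 day ETc forecasts (HS and PM
#'   paths) with accumulated totals.
#' * `evaluate` -- score forecasts against the one-step best estimate and
#'   write per-site skill plus across-site box-plot summaries.
#'
#' Outputs are deterministic for fixed inputs and seed; a `manifest.json`
#' (configuration hash, seed, package version) is written on every run, and
#' a command's outputs are removed again if it fails midway.
#'
#' @param config Configuration list ([default_config()] or [load_config()]).
#' @param command One of `"simulate"`, `"retrieve-canopy"`, `"calibrate"`,
#'   `"forecast"`, `"evaluate"`.
#' @param dir Run directory (created if missing).
#' @return Invisibly, the paths written by the command.
#' @export
run_pipeline <- function(config = default_config(),
                         command = c("simulate", "retrieve-canopy",
                                     "calibrate", "forecast", "evaluate"),
                         dir = ".") {
  command <- arg_match(command)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(name) file.path(dir, config$paths[[name]])
  written <- character()
  result <- tryCatch(
    switch(command,
      "simulate" = {
        sim <- config$simulate
        clim <- head(campania_climatology(), sim$n_sites)
        sites <- clim %>% select(all_of(c("site_id", "lat", "lon", "elev_m")))
        dates <- c(irrigation_season((sim$year - 4):(sim$year - 1)),
                   irrigation_season(sim$year))
        wx <- sim_weather(clim, dates, seed = sim$seed + 1L)
        fc <- sim_forecast_daily(wx, forecast_error_model(),
                                 seed = sim$seed + 2L, leads = sim$leads)
        refl <- bind_rows(
          sim_canopy(year = sim$year, field_id = "field01",
                     clair = config_clair(config), spec = config_sensor(config),
                     sampling_interval = 7),
          sim_canopy(year = sim$year, field_id = "field02", lai_max = 3.5,
                     clair = config_clair(config), spec = config_sensor(config),
                     sampling_interval = 15)
        ) %>%
          mutate(sensor_id = config$sensor$sensor_id) %>%
          select(all_of(c("field_id", "date", "sensor_id", "rho_red", "rho_nir")),
                 any_of("rho_green"))
        readr::write_csv(sites, p("sites")); written <- c(written, p("sites"))
        readr::write_csv(wx, p("weather")); written <- c(written, p("weather"))
        readr::write_csv(fc, p("forecasts")); written <- c(written, p("forecasts"))
        readr::write_csv(refl, p("reflectance")); written <- c(written, p("reflectance"))
        written
      },
      "retrieve-canopy" = {
        refl <- read_pipeline_csv(p("reflectance"), "reflectance")
        canopy <- retrieve_canopy(refl, config_sensor(config), config_clair(config))
        readr::write_csv(canopy, p("canopy")); written <- c(written, p("canopy"))
        written
      },
      "calibrate" = {
        sites <- read_pipeline_csv(p("sites"), "sites")
        wx <- read_pipeline_csv(p("weather"), "weather")
        ref <- filter(wx, as.integer(format(as.Date(.data$date), "%Y")) <
                        config$simulate$year)
        pairs <- inner_join(
          et0_hargreaves(ref, sites, k_hs = 1) %>%
            select(all_of(c("site_id", "date")), et0_hs_unit = "et_mm"),
          et0_penman_monteith(ref, sites) %>%
            select(all_of(c("site_id", "date")), et0_pm = "et_mm"),
          by = c("site_id", "date")
        )
        fit <- calibrate_khs(pairs, min_days = config$calibration$min_days)
        write_khs(fit, p("khs")); written <- c(written, p("khs"))
        fc <- read_pipeline_csv(p("forecasts"), "forecasts")
        fc$issue_date <- as.Date(fc$issue_date)
        bias <- fit_mean_bias(fc, ref, variable = "T",
                              reference_period = as.Date(ref$date))
        write_bias_table(bias, p("bias")); written <- c(written, p("bias"))
        written
      },
      "forecast" = {
        sites <- read_pipeline_csv(p("sites"), "sites")
        wx <- read_pipeline_csv(p("weather"), "weather")
        canopy <- read_pipeline_csv(p("canopy"), "canopy")
        khs <- jsonlite::read_json(p("khs"), simplifyVector = TRUE) %>% as_tibble()
        bias <- read_bias_table(p("bias"))
        fc <- read_pipeline_csv(p("forecasts"), "forecasts")
        fc$issue_date <- as.Date(fc$issue_date)
        eval_year <- config$simulate$year
        fc <- filter(fc, as.integer(format(.data$issue_date, "%Y")) == eval_year)
        fc <- apply_bias_correction(fc, bias)
        wx_eval <- filter(wx, as.integer(format(as.Date(.data$date), "%Y")) == eval_year)
        out <- purrr::map(split(canopy, canopy$field_id), function(cn) {
          cn$date <- as.Date(cn$date)
          kc <- crop_coefficient(wx_eval, cn, sites,
                                 h_c = config$forecast$h_c, on_undefined = "drop")
          fcf <- forecast_etc(kc, fc, sites, canopy = cn, k_hs = khs,
                              method = config$forecast$method,
                              h_c = config$forecast$h_c)
          acc <- accumulate_horizons(fcf, horizons = config$forecast$horizons) %>%
            tidyr::pivot_wider(
              names_from = "horizon",
              values_from = dplyr::ends_with("_acc"),
              names_glue = "{.value}{horizon}"
            )
          names(acc) <- sub("^etc_(hs|pm)_mm_acc(\\d+)$", "acc\\2_\\1_mm", names(acc))
          inner_join(fcf, acc, by = intersect(names(fcf), names(acc)))
        }) %>% bind_rows()
        readr::write_csv(out, p("forecast_out")); written <- c(written, p("forecast_out"))
        written
      },
      "evaluate" = {
        sites <- read_pipeline_csv(p("sites"), "sites")
        wx <- read_pipeline_csv(p("weather"), "weather")
        canopy <- read_pipeline_csv(p("canopy"), "canopy")
        fc <- readr::read_csv(p("forecast_out"), show_col_types = FALSE, progress = FALSE)
        fc$issue_date <- as.Date(fc$issue_date)
        eval_year <- config$simulate$year
        wx_eval <- filter(wx, as.integer(format(as.Date(.data$date), "%Y")) == eval_year)
        best <- purrr::map(split(canopy, canopy$field_id), function(cn) {
          cn$date <- as.Date(cn$date)
          etc_penman_monteith(wx_eval, cn, sites, h_c = config$forecast$h_c) %>%
            select(all_of(c("site_id", "date")), etc_obs_mm = "et_mm") %>%
            mutate(field_id = cn$field_id[1])
        }) %>% bind_rows()
        pairs <- fc %>%
          mutate(valid_date = .data$issue_date + .data$lead) %>%
          inner_join(best, by = c("field_id", "site_id", "valid_date" = "date"))
        skill <- bind_rows(
          skill_scores(pairs, "etc_hs_mm", "etc_obs_mm",
                       by = c("field_id", "site_id", "lead")) %>%
            mutate(method = "etc_hs"),
          skill_scores(pairs, "etc_pm_mm", "etc_obs_mm",
                       by = c("field_id", "site_id", "lead")) %>%
            mutate(method = "etc_pm")
        )
        readr::write_csv(skill, p("skill")); written <- c(written, p("skill"))
        summary <- skill %>%
          group_by(.data$method, .data$lead) %>%
          dplyr::group_modify(~ summarize_over_sites(.x, "rmse")) %>%
          ungroup() %>%
          select(-all_of("outliers"))
        jsonlite::write_json(summary, p("summary"), auto_unbox = TRUE, digits = NA)
        written <- c(written, p("summary"))
        written
      }
    ),
    error = function(e) {
      unlink(written)
      abort(sprintf("Pipeline command '%s' failed: %s", command,
                    conditionMessage(e)), parent = e)
    }
  )
  manifest <- list(
    command = command,
    config_hash = rlang::hash(config),
    seed = config$simulate$seed,
    package_version = as.character(utils::packageVersion("cropet"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(result)
}
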