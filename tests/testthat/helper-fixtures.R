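# Shared fixtures: everything is generated in code, nothing is stored.

# two inland/coastal stations with contrasting elevation and wind
tiny_sites <- function() {
  tibble::tibble(
    site_id = c("aws_a", "aws_b"),
    lat = c(40.9, 41.2),
    lon = c(14.3, 15.1),
    elev_m = c(50, 600)
  )
}

tiny_clim <- function() {
  dplyr::bind_cols(
    tiny_sites(),
    tibble::tibble(
      mean_t = c(24, 21), mean_ws10 = c(2.0, 3.5), mean_rh = c(70, 68),
      mean_rs_wm2 = c(265, 255)
    )
  )
}

# one fixed mid-summer day, chosen to sit well inside every validity range
fixed_weather_row <- function(site_id = "aws_a") {
  tibble::tibble(
    site_id = site_id, date = as.Date("2014-07-15"),
    t_max = 32, t_min = 18, t_mean = 25, rh_mean = 65, ws10 = 2.5,
    rs_wm2 = 300, pressure_kpa = NA_real_
  )
}

# random weather within the physical envelope the estimators accept
random_weather <- function(n, seed = 1, site_id = "aws_a") {
  withr::with_seed(seed, {
    t_min <- runif(n, 5, 25)
    drange <- runif(n, 2, 18)
    tibble::tibble(
      site_id = site_id,
      date = as.Date("2014-06-01") + (seq_len(n) - 1) %% 122,
      t_min = t_min,
      t_max = t_min + drange,
      rh_mean = runif(n, 20, 100),
      ws10 = runif(n, 0, 8),
      rs_wm2 = runif(n, 5, 350),
      pressure_kpa = NA_real_
    )
  })
}

# canopy series with a single pre-season acquisition (state constant all season)
constant_canopy <- function(lai = 3, albedo = 0.18) {
  tibble::tibble(date = as.Date("2014-05-20"), lai = lai, albedo = albedo)
}

# turn observed weather into a "perfect" daily forecast table for given leads
forecasts_from_obs <- function(wx, leads = 1:5) {
  purrr::map(split(wx, wx$site_id), function(tr) {
    tr <- dplyr::arrange(tr, date)
    ok <- vapply(tr$date, function(d) all((d + leads) %in% tr$date), logical(1))
    tidyr::expand_grid(issue_date = tr$date[ok], lead = as.integer(leads)) |>
      dplyr::mutate(valid_date = issue_date + lead) |>
      dplyr::inner_join(tr, by = c("valid_date" = "date")) |>
      dplyr::select(site_id, issue_date, lead, t_mean, t_max, t_min,
                    rh_mean, ws10, rs_wm2, pressure_kpa)
  }) |> dplyr::bind_rows()
}
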