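test_that("generators are fully deterministic under a fixed seed", {
  clim <- tiny_clim()
  dates <- irrigation_season(2014)[1:30]
  a <- sim_weather(clim, dates, seed = 91)
  b <- sim_weather(clim, dates, seed = 91)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$t_mean,
                                sim_weather(clim, dates, seed = 92)$t_mean)))
  fa <- sim_forecast_daily(a, seed = 93)
  fb <- sim_forecast_daily(b, seed = 93)
  expect_identical(fa, fb)
  ma <- sim_forecast_members(a[a$site_id == "aws_a", ][1:10, ], seed = 94,
                             leads = 1:2)
  mb <- sim_forecast_members(b[b$site_id == "aws_a", ][1:10, ], seed = 94,
                             leads = 1:2)
  expect_identical(ma, mb)
})

test_that("generated weather honours the site climatology and physics", {
  clim <- tiny_clim()
  wx <- sim_weather(clim, irrigation_season(2010:2013), seed = 95)
  by_site <- wx |>
    dplyr::group_by(site_id) |>
    dplyr::summarise(t_bar = mean(t_mean), .groups = "drop") |>
    dplyr::inner_join(clim, by = "site_id")
  # long-run mean temperature within 0.3 degC of the climatology
  expect_true(all(abs(by_site$t_bar - by_site$mean_t) < 0.3))
  expect_true(all(wx$t_min <= wx$t_mean & wx$t_mean <= wx$t_max))
  expect_true(all(wx$rh_mean >= 0 & wx$rh_mean <= 100))
  expect_true(all(wx$ws10 > 0))
  # shortwave radiation never exceeds the clear-sky envelope
  wx2 <- dplyr::inner_join(wx, clim, by = "site_id")
  doy <- as.integer(strftime(wx2$date, "%j"))
  cap <- (0.75 + 2e-5 * wx2$elev_m) *
    extraterrestrial_radiation(wx2$lat, doy) / 0.0864
  expect_true(all(wx2$rs_wm2 <= cap + 1e-9))
  expect_error(sim_weather(clim, as.Date(character()), seed = 1), "non-empty")
})

test_that("a degenerate error model returns truth plus bias exactly", {
  clim <- tiny_clim()[1, ]
  wx <- sim_weather(clim, irrigation_season(2014)[1:20], seed = 96)
  m0 <- forecast_error_model(
    sd = c(T = 0, RH = 0, WS10 = 0, RS = 0, P = 0), members = 4
  )
  fc <- sim_forecast_daily(wx, m0, seed = 97) |>
    dplyr::mutate(valid_date = issue_date + lead) |>
    dplyr::inner_join(
      dplyr::select(wx, site_id, date, obs_t = t_mean, obs_rh = rh_mean,
                    obs_rs = rs_wm2),
      by = c("site_id", "valid_date" = "date")
    )
  expect_equal(fc$t_mean, fc$obs_t - 0.68, tolerance = 1e-12)
  expect_equal(fc$rh_mean, fc$obs_rh, tolerance = 1e-12)
  expect_equal(fc$rs_wm2, fc$obs_rs, tolerance = 1e-12)
  # the member-level chain collapses the same way through reduce_daily
  mem <- sim_forecast_members(wx[1:12, ], m0, seed = 98, leads = 1:2)
  red <- reduce_daily(mem) |>
    dplyr::mutate(valid_date = issue_date + lead) |>
    dplyr::inner_join(dplyr::select(wx, site_id, date, obs_t = t_mean,
                                    obs_rs = rs_wm2),
                      by = c("site_id", "valid_date" = "date"))
  expect_equal(red$t_mean, red$obs_t - 0.68, tolerance = 1e-9)
  expect_equal(red$rs_wm2, red$obs_rs, tolerance = 1e-9)
})

test_that("the injected temperature bias is recovered from reference seasons", {
  clim <- tiny_clim()
  wx <- sim_weather(clim, irrigation_season(2010:2013), seed = 99)
  fc <- sim_forecast_daily(wx, forecast_error_model(), seed = 100)
  bt <- fit_mean_bias(fc, wx, "T")
  # pooled across sites and leads the Monte-Carlo error is a few hundredths
  expect_equal(mean(bt$mean_bias), -0.68, tolerance = 0.05)
  # each entry individually sits within its own sampling error
  g <- 1 + 0.2 * (bt$lead - 1)
  expect_true(all(abs(bt$mean_bias + 0.68) < 4 * g * 1.0 / sqrt(bt$n)))
})

test_that("the canopy season peaks at flowering and inverts exactly", {
  season <- sim_canopy(2014, sampling_interval = 1)
  doy <- as.integer(strftime(season$date, "%j"))
  expect_equal(season$lai[doy == 213], 5) # flowering day, by construction
  expect_equal(max(season$lai), 5)
  expect_true(all(season$lai >= 0))
  # albedo drifts with canopy closure between its configured bounds
  expect_equal(min(season$albedo) > 0.149, TRUE)
  expect_equal(max(season$albedo), 0.20, tolerance = 1e-12)
  # round trip through the CLAIR inversion at numerical precision
  lai_back <- retrieve_lai(season$rho_red, season$rho_nir, default_sensor(),
                           clair_params(0.35, 0.6))
  expect_equal(lai_back, season$lai, tolerance = 1e-9)
  # and the weekly/fortnightly variants used in the experiment
  for (iv in c(7, 15)) {
    s <- sim_canopy(2014, sampling_interval = iv, lai_max = 3.5)
    back <- retrieve_lai(s$rho_red, s$rho_nir, default_sensor(),
                         clair_params(0.35, 0.6))
    expect_equal(back, s$lai, tolerance = 1e-9)
  }
  expect_error(sim_canopy(2014, lai_max = 0), "lai_max")
  expect_error(sim_canopy(2014, albedo_range = c(0.2, 0.15)), "increasing")
})
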